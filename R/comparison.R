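#' Manhattan distance between two profiles
#'
#' The dissimilarity score used for alignment-free sequence comparison: the
#' sum of absolute count differences over all cells (all `3 * 2^k` cells of
#' a PC-mer profile, or all `4^k` cells of an FCGR profile).
#'
#' @param a,b two profiles of the same class, `k`, counting mode and
#'   normalization state.
#' @return a non-negative number.
#' @export
manhattan_distance <- function(a, b) {
  check_comparable(a, b)
  sum(abs(unlist(a$counts, use.names = FALSE) -
          unlist(b$counts, use.names = FALSE)))
}

check_comparable <- function(a, b) {
  stopifnot(inherits(a, c("pcmer_profile", "fcgr_profile")),
            inherits(b, c("pcmer_profile", "fcgr_profile")))
  if (class(a)[1L] != class(b)[1L])
    stop("profiles must be of the same type")
  if (a$k != b$k)
    stop("profiles have different k: ", a$k, " vs ", b$k)
  if (a$mode != b$mode)
    stop("profiles have different counting modes: ", a$mode, " vs ", b$mode)
  if (isTRUE(a$normalized) != isTRUE(b$normalized))
    stop("profiles differ in normalization state")
  invisible(TRUE)
}

#' Pairwise Manhattan distance matrix
#'
#' @param profiles a list of at least two profiles (uniform class, `k`,
#'   mode, normalization).
#' @param ids row/column ids; defaults to the profiles' stored ids, else
#'   `seq_1, seq_2, ...`.
#' @return a symmetric n x n numeric matrix with zero diagonal and `ids` as
#'   dimnames.
#' @export
pairwise_distances <- function(profiles, ids = NULL) {
  if (length(profiles) < 2L)
    stop("need at least two profiles")
  for (p in profiles[-1L]) check_comparable(profiles[[1L]], p)
  if (is.null(ids)) {
    ids <- vapply(seq_along(profiles), function(i)
      as.character(profiles[[i]]$id %||% paste0("seq_", i)), character(1L))
  }
  stopifnot(length(ids) == length(profiles))
  x <- do.call(rbind, lapply(profiles, function(p)
    unlist(p$counts, use.names = FALSE)))
  d <- as.matrix(stats::dist(x, method = "manhattan"))
  dimnames(d) <- list(ids, ids)
  d
}

#' Leave-one-out retrieval AUC of a distance matrix
#'
#' Scores how well small distances predict shared class membership: each
#' sequence in turn is a query, all others are ranked by ascending distance,
#' same-label sequences are the positives, and the ROC AUC of that ranking
#' is computed (ties by midrank, so an all-tied matrix scores 0.5). The
#' returned value is the unweighted mean over queries. Queries whose class
#' has no other member are excluded with a warning.
#'
#' @param dmat symmetric distance matrix (e.g. from [pairwise_distances()]).
#' @param labels class label per row of `dmat`.
#' @return mean AUC in `[0, 1]`.
#' @export
retrieval_auc <- function(dmat, labels) {
  stopifnot(is.matrix(dmat), nrow(dmat) == ncol(dmat),
            length(labels) == nrow(dmat))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("retrieval AUC needs at least two classes")
  n <- nrow(dmat)
  singleton <- table(labels)[labels] == 1L
  if (any(singleton))
    warning("excluding ", sum(singleton),
            " query/queries from singleton classes: ",
            paste(unique(labels[singleton]), collapse = ", "))
  aucs <- vapply(which(!singleton), function(i) {
    d <- dmat[i, -i]
    pos <- labels[-i] == labels[i]
    n1 <- sum(pos)
    n0 <- sum(!pos)
    r <- rank(-d)  # higher rank = smaller distance = more similar
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1L))
  mean(aucs)
}

#' Pearson correlation between two distance matrices
#'
#' Computed over the strict upper-triangle entries of two matrices indexed
#' by the same sequences in the same order; used to compare an
#' alignment-free distance against a reference dissimilarity.
#'
#' @param a,b two distance matrices with identical ids (dimnames) in
#'   identical order.
#' @return Pearson correlation in `[-1, 1]`, or `NA` with a warning when
#'   either triangle has zero variance.
#' @export
matrix_correlation <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (!all(dim(a) == dim(b)))
    stop("distance matrices differ in size: ", nrow(a), " vs ", nrow(b))
  if (nrow(a) < 3L)
    stop("need at least 3 sequences for a distance-matrix correlation")
  ia <- rownames(a)
  ib <- rownames(b)
  if (!is.null(ia) && !is.null(ib) && !identical(ia, ib)) {
    bad <- which(ia != ib)
    stop("distance-matrix ids mismatch at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), ": ",
         paste(utils::head(paste0(ia[bad], " != ", ib[bad]), 5L),
               collapse = "; "))
  }
  ut <- upper.tri(a)
  va <- a[ut]
  vb <- b[ut]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero variance in a distance matrix; correlation undefined")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

#' Distance-based comparison report
#'
#' Bundles the two evaluation numbers for a distance matrix over a labeled
#' sequence set: the leave-one-out retrieval AUC against the labels and,
#' when a reference matrix is supplied, the Pearson correlation between the
#' two matrices' upper triangles.
#'
#' @param dmat distance matrix.
#' @param labels class label per row.
#' @param reference optional reference distance matrix (same ids/order).
#' @return a `comparison_report`: list with `auc`, `correlation` (NULL if no
#'   reference) and `n`.
#' @export
comparison_report <- function(dmat, labels, reference = NULL) {
  rep <- list(auc = retrieval_auc(dmat, labels),
              correlation = if (!is.null(reference))
                matrix_correlation(dmat, reference),
              n = nrow(dmat))
  structure(rep, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparison report over %d sequences\n", x$n))
  cat(sprintf("  retrieval AUC: %.4f\n", x$auc))
  if (!is.null(x$correlation))
    cat(sprintf("  correlation with reference distances: %.4f\n",
                x$correlation))
  invisible(x)
}

#' Read/write a distance matrix as TSV
#'
#' Serialized with an id header row and a leading id column.
#'
#' @param dmat distance matrix with ids as dimnames.
#' @param path file path.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns the matrix.
#' @export
write_distance_matrix <- function(dmat, path) {
  df <- data.frame(id = rownames(dmat), dmat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(id = "character"))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$id
  m
}
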