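#' Read sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a record
#' table. Residues are upper-cased and RNA `U` is mapped to `T`; IUPAC
#' ambiguity codes are preserved as-is — their handling is decided at
#' encoding time, not at I/O time. Record ids are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns `id` and `seq`, one row per record in
#'   file order; zero rows for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0L)
    return(data.frame(id = character(), seq = character(),
                      stringsAsFactors = FALSE))
  is_header <- startsWith(trimws(lines), ">")
  if (!is_header[meaningful[1L]])
    stop("malformed FASTA at line ", meaningful[1L],
         ": sequence data before the first '>' header")
  headers <- meaningful[is_header[meaningful]]
  for (h in headers) {
    if (!nzchar(trimws(sub("^>", "", trimws(lines[h])))))
      stop("malformed FASTA at line ", h, ": header with no identifier")
    nxt <- meaningful[meaningful > h]
    if (length(nxt) == 0L || is_header[nxt[1L]])
      stop("malformed FASTA at line ", h, ": entry with an empty body")
  }
  recs <- seqinr::read.fasta(path, as.string = TRUE, seqtype = "DNA",
                             forceDNAtolower = FALSE)
  ids <- names(recs)
  if (anyDuplicated(ids))
    stop("duplicate record ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(id = ids,
             seq = normalize_residues(vapply(recs, as.character,
                                             character(1L))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records a data.frame with columns `id` and `seq` (as returned by
#'   [read_fasta()]) .
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  seqinr::write.fasta(as.list(records$seq), names = records$id,
                      file.out = path, nbchar = width, as.string = TRUE)
  invisible(path)
}

#' Read an id-to-label mapping from a two-column TSV
#'
#' The canonical label source: a header-less tab-separated file with the
#' record id in column 1 and the class label in column 2.
#'
#' @param path path to the TSV file.
#' @return a named character vector (names = ids, values = labels).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("id", "label"))
  if (anyDuplicated(tab$id))
    stop("duplicate ids in label mapping: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  stats::setNames(tab$label, tab$id)
}

#' @rdname read_labels
#' @param labels named character vector of labels.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(id = names(labels), label = unname(labels)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse class labels from FASTA header tokens
#'
#' Fallback label convention for datasets without a mapping file: the label
#' is the last `|`-delimited token of the record id (e.g.
#' `>read42|Acetobacter`).
#'
#' @param ids character vector of record ids.
#' @return a named character vector mapping each id to its label.
#' @export
labels_from_headers <- function(ids) {
  no_bar <- !grepl("|", ids, fixed = TRUE)
  if (any(no_bar))
    stop("ids without a '|'-delimited label token: ",
         paste(ids[no_bar], collapse = ", "))
  stats::setNames(sub(".*\\|", "", ids), ids)
}

#' Attach class labels to sequence records
#'
#' Joins an id-to-label mapping onto a record table, preserving record
#' order. Every record id must be present in the mapping; mapping entries
#' for absent ids are ignored.
#'
#' @param records a data.frame with columns `id` and `seq`.
#' @param mapping a named character vector (names = ids) or a two-column
#'   data.frame (id, label).
#' @param level_name free-text tag for the labelling, e.g. `"genus"`.
#' @return a `labeled_dataset`: list with `records`, `labels` (character,
#'   aligned to record order) and `level_name`.
#' @export
attach_labels <- function(records, mapping, level_name = "class") {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (is.data.frame(mapping)) {
    stopifnot(ncol(mapping) >= 2L)
    mapping <- stats::setNames(as.character(mapping[[2L]]),
                               as.character(mapping[[1L]]))
  }
  if (is.null(names(mapping)) || anyDuplicated(names(mapping)))
    stop("'mapping' must be uniquely named by record id")
  missing <- setdiff(records$id, names(mapping))
  if (length(missing))
    stop("no label for record(s): ", paste(missing, collapse = ", "))
  labeled_dataset(records, unname(mapping[records$id]), level_name)
}

#' Construct a labeled dataset
#'
#' @param records data.frame with columns `id` and `seq`; ids unique.
#' @param labels character vector, one label per record.
#' @param level_name free-text tag for the labelling level.
#' @return a `labeled_dataset` object.
#' @export
labeled_dataset <- function(records, labels, level_name = "class") {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)),
            length(labels) == nrow(records))
  if (anyDuplicated(records$id))
    stop("record ids must be unique")
  structure(list(records = records, labels = as.character(labels),
                 level_name = level_name),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled dataset: %d sequences, %d classes (level: %s)\n",
              nrow(x$records), length(unique(x$labels)), x$level_name))
  print(utils::head(table(label = x$labels)))
  invisible(x)
}

#' Write PC-mer profiles as a tab-separated feature matrix
#'
#' One row per sequence: an `id` column followed by the `3 * 2^k` feature
#' columns in the fixed block order purine_pyrimidine, amino_keto,
#' weak_strong, each block ordered by chaos-game cell index `1..2^k`;
#' columns are named `<block>_<index>`. Integer counts round-trip
#' losslessly through [read_feature_matrix()].
#'
#' @param profiles list of `pcmer_profile` objects sharing one `k`.
#' @param ids character vector of row ids (defaults to profile ids).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_feature_matrix <- function(profiles, ids = NULL, path) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1L), "pcmer_profile")))
  ks <- vapply(profiles, function(p) p$k, integer(1L))
  if (length(unique(ks)) != 1L)
    stop("profiles mix k values: ", paste(unique(ks), collapse = ", "))
  if (is.null(ids))
    ids <- vapply(profiles, function(p) as.character(p$id %||% NA_character_),
                  character(1L))
  if (anyNA(ids) || length(ids) != length(profiles))
    stop("'ids' must supply one id per profile")
  mat <- do.call(rbind, lapply(profiles, feature_vector))
  df <- data.frame(id = ids, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @return `read_feature_matrix()` returns a numeric matrix with row names
#'   = ids and the serialized column names.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(id = "character"))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$id
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
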