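#' Classical four-letter FCGR encoding
#'
#' The frequency-of-chaos-game-representation baseline: the four-letter
#' analogue of [encode_pcmer()]. Nucleotides are coded A=0, C=1, G=2, T=3
#' and walked on cells `1..4^k` by the base-4 recurrence
#' `x' = floor(x / 4) + digit * 4^(k-1)` (with `x = index - 1`), starting
#' from the vector midpoint `4^k / 2`. In `kmer_only` mode each cell counts
#' exactly one nucleotide k-mer; the cell-to-k-mer bijection is
#' [fcgr_kmer_of_cell()] (most recent base = most significant base-4 digit).
#' Ambiguity codes reset the walk exactly as in [encode_pcmer()].
#'
#' @inheritParams encode_pcmer
#' @param k word length, `1 <= k <= 12` (the profile has `4^k` cells).
#' @return an `fcgr_profile`: list with `k`, `mode`, `counts` (integer
#'   vector of length `4^k`), `positions_counted`, `normalized`, `id`.
#' @examples
#' encode_fcgr("ACGT", k = 1)$counts  # one of each base
#' @export
encode_fcgr <- function(seq, k, mode = c("all_positions", "kmer_only"),
                        id = NULL) {
  mode <- match.arg(mode)
  check_k(k, max = 12L)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("'seq' must be a single non-empty nucleotide string")
  d <- seq_digits(normalize_residues(seq))
  counts <- cgr_walk(d, 4L, as.integer(k), mode)
  structure(list(k = as.integer(k), mode = mode, counts = counts,
                 positions_counted = sum(counts),
                 normalized = FALSE, id = id),
            class = "fcgr_profile")
}

#' Cell/k-mer bijection of the FCGR profile
#'
#' In `kmer_only` mode, cell `c` of an [encode_fcgr()] profile counts the
#' k-mer whose base at window position `t` (1 = oldest, `k` = most recent)
#' is the base-4 digit of weight `4^(t-1)` in `c - 1`, under A=0, C=1, G=2,
#' T=3. `fcgr_cell_of_kmer()` is the inverse.
#'
#' @param cell cell index in `1..4^k`.
#' @param k word length.
#' @param kmer nucleotide string of length `k`.
#' @return the k-mer string, respectively the cell index.
#' @examples
#' fcgr_kmer_of_cell(1, 2)            # "AA"
#' fcgr_cell_of_kmer("CA")            # most recent base A: low digit block
#' @export
fcgr_kmer_of_cell <- function(cell, k) {
  check_k(k, max = 12L)
  stopifnot(all(cell >= 1), all(cell <= 4^k))
  nts <- c("A", "C", "G", "T")
  vapply(cell, function(cc) {
    v <- cc - 1
    digits <- (v %/% 4^(0:(k - 1))) %% 4    # digits[t] = window position t
    paste(nts[digits + 1], collapse = "")
  }, character(1L))
}

#' @rdname fcgr_kmer_of_cell
#' @export
fcgr_cell_of_kmer <- function(kmer) {
  vapply(kmer, function(km) {
    d <- seq_digits(normalize_residues(km))
    if (anyNA(d)) stop("'kmer' must contain only A/C/G/T: ", km)
    k <- length(d)
    as.integer(1 + sum(d * 4^(seq_len(k) - 1)))
  }, integer(1L), USE.NAMES = FALSE)
}

#' Collapse an FCGR spectrum into a PC-mer profile
#'
#' The exact relation between the two encodings: the `4^k` classical k-mers
#' fall, per grouping scheme, into `2^k` classes of `2^k` members — all
#' k-mers whose per-position physicochemical images coincide. Summing the
#' FCGR counts over each class reproduces the PC-mer vector, so
#' `group_collapse(encode_fcgr(s, k, "kmer_only"))` equals
#' `encode_pcmer(s, k, "kmer_only")` for every sequence.
#'
#' @param fcgr an `fcgr_profile` in `kmer_only` mode (only there do cells
#'   correspond to complete k-mers).
#' @return a `pcmer_profile` with the same `k`, `positions_counted` and
#'   normalization state.
#' @export
group_collapse <- function(fcgr) {
  stopifnot(inherits(fcgr, "fcgr_profile"))
  if (fcgr$mode != "kmer_only")
    stop("group_collapse() requires an fcgr_profile in 'kmer_only' mode")
  k <- fcgr$k
  size <- as.integer(4^k)
  x <- 0:(size - 1)
  counts <- lapply(.scheme_names, function(nm) {
    bits <- .scheme_bits[, nm]
    collapsed <- integer(size)
    for (t in seq_len(k)) {
      digit <- (x %/% 4^(t - 1)) %% 4
      collapsed <- collapsed + bits[digit + 1] * 2^(t - 1)
    }
    v <- rowsum(as.numeric(fcgr$counts), collapsed)[, 1L]
    if (isTRUE(fcgr$normalized)) unname(v) else as.integer(v)
  })
  names(counts) <- .scheme_names
  structure(list(k = k, mode = "kmer_only", counts = counts,
                 positions_counted = fcgr$positions_counted,
                 normalized = isTRUE(fcgr$normalized), id = fcgr$id),
            class = "pcmer_profile")
}

#' @export
print.fcgr_profile <- function(x, ...) {
  cat(sprintf("FCGR profile%s: k = %d, mode = %s, %d features (4^%d)\n",
              if (is.null(x$id)) "" else paste0(" [", x$id, "]"),
              x$k, x$mode, 4L^x$k, x$k))
  cat(sprintf("  positions counted: %s%s\n", x$positions_counted,
              if (x$normalized) " (normalized to frequencies)" else ""))
  invisible(x)
}
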