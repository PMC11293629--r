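#' Normalize nucleotide residues
#'
#' Upper-cases a nucleotide string and maps RNA `U` to DNA `T`, so DNA and
#' RNA inputs are treated uniformly. Ambiguity codes (`N`, `R`, `Y`, ...) are
#' preserved; how they are handled is decided at encoding time.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector, upper-case, `U` replaced by `T`.
#' @export
normalize_residues <- function(x) chartr("U", "T", toupper(x))

# byte -> digit code A=0, C=1, G=2, T=3; anything else NA (break).
# Input is assumed normalized (upper-case, U->T).
.byte_digit <- local({
  tab <- rep(NA_integer_, 256L)
  tab[as.integer(charToRaw("A")) + 1L] <- 0L
  tab[as.integer(charToRaw("C")) + 1L] <- 1L
  tab[as.integer(charToRaw("G")) + 1L] <- 2L
  tab[as.integer(charToRaw("T")) + 1L] <- 3L
  tab
})

# nucleotide string -> integer digits 0..3 with NA at ambiguity codes
seq_digits <- function(seq) {
  .byte_digit[as.integer(charToRaw(seq)) + 1L]
}

#' Re-alphabet a sequence under a physicochemical grouping scheme
#'
#' Maps each residue of a (normalized) nucleotide string to the scheme's
#' two-letter alphabet: e.g. under `purine_pyrimidine`, `A`/`G` become `R`
#' and `C`/`T` become `Y`. Residues outside `A`/`C`/`G`/`T` (IUPAC ambiguity
#' codes such as `N`) become the break sentinel `"x"`, at which the
#' chaos-game walk resets (see [encode_pcmer()]).
#'
#' @param seq a single nucleotide string (normalized with
#'   [normalize_residues()] first if needed).
#' @param scheme a [grouping_scheme()] object or scheme name.
#' @return a string over `{low_symbol, high_symbol, "x"}` of the same length.
#' @examples
#' transform_sequence("ATCGTA", "purine_pyrimidine")  # "RYYRYR"
#' @export
transform_sequence <- function(seq, scheme) {
  if (is.character(scheme)) scheme <- grouping_scheme(scheme)
  stopifnot(inherits(scheme, "grouping_scheme"),
            is.character(seq), length(seq) == 1L)
  d <- seq_digits(normalize_residues(seq))
  bits <- .scheme_bits[, scheme$name][d + 1L]
  out <- ifelse(is.na(bits), .break_sentinel,
                ifelse(bits == 1L, scheme$high_symbol, scheme$low_symbol))
  paste(out, collapse = "")
}

#' One step of the one-dimensional chaos-game walk
#'
#' The walk lives on cells `1..2^k`. Reading one binary symbol moves the
#' current cell halfway toward the symbol's endpoint — 0 for the low symbol,
#' `2^k` for the high symbol — with ceiling rounding:
#' `index' = ceiling((index + endpoint) / 2)`.
#'
#' After `k` steps from any start the cell identifies the last `k` symbols
#' uniquely (the walk enumerates binary k-mers; the most recent symbol is
#' the most significant bit of `index - 1`).
#'
#' @param index current cell, integer in `[1, 2^k]`.
#' @param endpoint 0 (low symbol) or `2^k` (high symbol).
#' @param k word length.
#' @return the updated cell index, in `[1, 2^k]`.
#' @examples
#' cgr_step(2, 0, k = 2)  # 1
#' cgr_step(1, 4, k = 2)  # 3
#' @export
cgr_step <- function(index, endpoint, k) {
  size <- 2^k
  if (!endpoint %in% c(0, size))
    stop("endpoint must be 0 or 2^k = ", size)
  if (index < 1 || index > size)
    stop("index must lie in [1, ", size, "]")
  ceiling((index + endpoint) / 2)
}

# Generic chaos-game walk over digit codes 0..(base-1); NA is a break:
# the walk resets to the start cell and (in kmer_only mode) the window
# counter restarts. Works in 0-based coordinates x = index - 1, where the
# update is x' = floor(x / base) + digit * base^(k-1), the exact equivalent
# of index' = ceiling((index + digit * base^k) / base). Start cell is the
# vector midpoint index = base^k / 2.
cgr_walk <- function(digits, base, k, mode) {
  size <- as.integer(base^k)
  shift <- size %/% as.integer(base)         # base^(k-1)
  start <- size %/% 2L - 1L                  # midpoint, 0-based
  counts <- integer(size)
  all_pos <- identical(mode, "all_positions")
  x <- start
  run <- 0L
  if (anyNA(digits)) {
    for (d in digits) {
      if (is.na(d)) {
        x <- start
        run <- 0L
        next
      }
      x <- x %/% as.integer(base) + d * shift
      run <- run + 1L
      if (all_pos || run >= k) counts[x + 1L] <- counts[x + 1L] + 1L
    }
  } else {
    b <- as.integer(base)
    for (d in digits) {
      x <- x %/% b + d * shift
      run <- run + 1L
      if (all_pos || run >= k) counts[x + 1L] <- counts[x + 1L] + 1L
    }
  }
  counts
}

#' PC-mer encoding of a nucleotide sequence
#'
#' Computes the PC-mer profile: for each of the three physicochemical
#' grouping schemes (purine/pyrimidine, amino/keto, weak/strong) the
#' sequence is re-alphabeted to two symbols and profiled by the
#' one-dimensional chaos game of [cgr_step()], giving one count vector of
#' length `2^k` per scheme — `3 * 2^k` features in total, versus `4^k` for
#' the classical k-mer/FCGR spectrum.
#'
#' Starting from the vector midpoint `2^k / 2`, each symbol moves the walk
#' halfway toward its endpoint and the landed cell is incremented. Two
#' counting modes are offered:
#'
#' * `"all_positions"`: increment at every position from the first. The
#'   first `k - 1` increments land in partial-prefix cells that do not
#'   correspond to complete k-mers.
#' * `"kmer_only"`: increment only once a full window of `k` symbols has
#'   been consumed; each cell then equals the count of one binary k-mer
#'   (see [brute_force_binary_kmer_counts()]).
#'
#' Ambiguity codes (any residue outside A/C/G/T after normalization) break
#' the walk: it resets to the midpoint and, in `kmer_only` mode, the window
#' counter restarts — the behaviour of a standard k-mer counter that splits
#' the sequence at ambiguous residues.
#'
#' @param seq a single nucleotide string (DNA or RNA; case-insensitive).
#' @param k word length, `1 <= k <= 24`.
#' @param mode `"all_positions"` (default) or `"kmer_only"`.
#' @param id optional sequence identifier stored in the profile.
#' @return a `pcmer_profile`: list with `k`, `mode`, `counts` (list of three
#'   integer vectors named `purine_pyrimidine`, `amino_keto`, `weak_strong`,
#'   each of length `2^k`, cells indexed `1..2^k`), `positions_counted`,
#'   `normalized` (FALSE) and `id`.
#' @examples
#' p <- encode_pcmer("ATCGTA", k = 2)
#' p$counts$purine_pyrimidine
#' @seealso [encode_fcgr()] for the 4-letter baseline, [group_collapse()]
#'   for the exact relation between the two.
#' @export
encode_pcmer <- function(seq, k, mode = c("all_positions", "kmer_only"),
                         id = NULL) {
  mode <- match.arg(mode)
  check_k(k, max = 24L)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("'seq' must be a single non-empty nucleotide string")
  d <- seq_digits(normalize_residues(seq))
  counts <- lapply(.scheme_names, function(nm) {
    bits <- .scheme_bits[, nm][d + 1L]
    cgr_walk(bits, 2L, as.integer(k), mode)
  })
  names(counts) <- .scheme_names
  structure(list(k = as.integer(k), mode = mode, counts = counts,
                 positions_counted = sum(counts[[1L]]),
                 normalized = FALSE, id = id),
            class = "pcmer_profile")
}

check_k <- function(k, max) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k))
    stop("'k' must be a positive integer")
  if (k > max)
    stop("'k' must be at most ", max)
  invisible(as.integer(k))
}

#' Brute-force binary k-mer counting
#'
#' Counts every overlapping window of length `k` in a two-symbol string by
#' direct substring extraction — the independent reference against which the
#' chaos-game encoder is verified. Window counts are placed at the cell the
#' walk of [cgr_step()] would reach: window position `t` (1 = oldest, `k` =
#' most recent) contributes `2^(t-1)` to `cell - 1` when that symbol is the
#' high symbol, so the most recent symbol is the most significant bit.
#'
#' @param x a string over a two-symbol alphabet (e.g. `"RYYRYR"`).
#' @param k window length.
#' @param high the high symbol (endpoint `2^k`). If `NULL`, inferred from
#'   the scheme alphabets: `Y`, `K` and `W` are high, `R`, `M` and `S` low.
#' @return integer vector of length `2^k`; all zeros when `nchar(x) < k`.
#' @examples
#' brute_force_binary_kmer_counts("RY", 2)    # cell 3 (R then Y) is 1
#' brute_force_binary_kmer_counts("RRRR", 2)  # cell 1 is 3
#' @export
brute_force_binary_kmer_counts <- function(x, k, high = NULL) {
  stopifnot(is.character(x), length(x) == 1L)
  check_k(k, max = 16L)  # enumeration of all 2^k words; a verification tool
  chars <- unique(strsplit(x, "")[[1L]])
  if (length(chars) > 2L)
    stop("'x' must use a two-symbol alphabet, got: ",
         paste(chars, collapse = ", "))
  partner <- c(Y = "R", K = "M", W = "S", R = "Y", M = "K", S = "W")
  if (is.null(high)) {
    hi <- chars[chars %in% c("Y", "K", "W")]
    lo <- chars[chars %in% c("R", "M", "S")]
    if (length(hi) > 1L || length(lo) > 1L ||
        length(c(hi, lo)) < length(chars) ||
        (length(hi) == 1L && length(lo) == 1L && partner[hi] != lo))
      stop("cannot infer the high symbol from alphabet {",
           paste(chars, collapse = ","), "}; pass 'high' explicitly")
    high <- if (length(hi)) hi else unname(partner[lo])
  }
  low <- setdiff(chars, high)
  if (length(low) > 1L)
    stop("'x' contains symbols other than 'high' and one low symbol")
  if (length(low) == 0L)
    low <- if (high %in% names(partner)) unname(partner[high]) else "_"
  size <- as.integer(2^k)
  counts <- integer(size)
  n <- nchar(x)
  if (n < k) return(counts)
  windows <- substring(x, 1:(n - k + 1L), k:n)
  cells <- binary_kmer_cells(k, high, low)
  hit <- cells[windows]
  tab <- tabulate(hit, nbins = size)
  tab
}

# named vector: binary k-mer string -> cell index, per the weighting above
binary_kmer_cells <- function(k, high, low) {
  size <- as.integer(2^k)
  cells <- 1:size
  kmers <- vapply(cells - 1L, function(v) {
    bits <- bitwAnd(v %/% 2^(0:(k - 1L)), 1L)  # bits[t] = window position t
    paste(ifelse(bits == 1L, high, low), collapse = "")
  }, character(1L))
  stats::setNames(cells, kmers)
}

#' Number of PC-mer and FCGR features
#'
#' The PC-mer profile concatenates three `2^k` vectors, `3 * 2^k` features;
#' the classical four-letter k-mer/FCGR spectrum has `4^k`. The ratio
#' `4^k / (3 * 2^k)` is the memory reduction of the grouped encoding.
#'
#' @param k word length.
#' @return feature count (double, since `4^k` exceeds integer range for
#'   large `k`).
#' @examples
#' pcmer_feature_length(12)  # 12288
#' fcgr_feature_length(12)   # 16777216
#' @export
pcmer_feature_length <- function(k) {
  check_k(k, max = 64L)
  3 * 2^k
}

#' @rdname pcmer_feature_length
#' @export
fcgr_feature_length <- function(k) {
  check_k(k, max = 64L)
  4^k
}

#' Concatenated feature vector of a profile
#'
#' Flattens a profile into the serialized feature order. For a
#' `pcmer_profile` the blocks come in the fixed order purine_pyrimidine,
#' amino_keto, weak_strong, each block ordered by chaos-game cell index
#' `1..2^k`; names are `<block>_<index>`. For an `fcgr_profile` the cells
#' come in walk order with names `fcgr_<index>`.
#'
#' @param profile a `pcmer_profile` or `fcgr_profile`.
#' @return named numeric vector.
#' @export
feature_vector <- function(profile) UseMethod("feature_vector")

#' @export
feature_vector.pcmer_profile <- function(profile) {
  v <- unlist(profile$counts, use.names = FALSE)
  names(v) <- unlist(lapply(.scheme_names, function(nm)
    paste0(nm, "_", seq_len(2^profile$k))))
  v
}

#' @export
feature_vector.fcgr_profile <- function(profile) {
  stats::setNames(profile$counts,
                  paste0("fcgr_", seq_along(profile$counts)))
}

#' Convert a profile to per-position frequencies
#'
#' Divides every count by `positions_counted`, turning counts into a
#' composition that is comparable across sequences of different lengths.
#' Profiles are raw counts by default.
#'
#' @param profile a `pcmer_profile` or `fcgr_profile`.
#' @return the profile with counts divided by `positions_counted` and
#'   `normalized = TRUE`.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, c("pcmer_profile", "fcgr_profile")))
  if (isTRUE(profile$normalized)) return(profile)
  if (profile$positions_counted == 0)
    stop("cannot normalize a profile with no counted positions")
  if (inherits(profile, "pcmer_profile")) {
    profile$counts <- lapply(profile$counts, function(v)
      v / profile$positions_counted)
  } else {
    profile$counts <- profile$counts / profile$positions_counted
  }
  profile$normalized <- TRUE
  profile
}

#' @export
print.pcmer_profile <- function(x, ...) {
  cat(sprintf("PC-mer profile%s: k = %d, mode = %s, %d features (3 x 2^%d)\n",
              if (is.null(x$id)) "" else paste0(" [", x$id, "]"),
              x$k, x$mode, 3L * 2L^x$k, x$k))
  cat(sprintf("  positions counted: %s%s\n", x$positions_counted,
              if (x$normalized) " (normalized to frequencies)" else ""))
  invisible(x)
}
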