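#' Physicochemical grouping schemes
#'
#' The three binary re-alphabetings of the nucleotide alphabet used by the
#' PC-mer encoding. Each scheme partitions \{A, C, G, T\} into two
#' physicochemical classes and names each class by its IUPAC degenerate
#' symbol:
#'
#' * `purine_pyrimidine`: purines A,G -> `R` (low endpoint), pyrimidines
#'   C,T -> `Y` (high endpoint) — ring structure.
#' * `amino_keto`: amino A,C -> `M` (low), keto G,T -> `K` (high) —
#'   functional group at the ring position facing the major groove.
#' * `weak_strong`: strong C,G -> `S` (low), weak A,T -> `W` (high) —
#'   three vs two hydrogen bonds.
#'
#' The low symbol is the endpoint mapped to 0 in the chaos-game walk, the
#' high symbol the endpoint mapped to `2^k` (see [cgr_step()]).
#'
#' @param name one of `"purine_pyrimidine"`, `"amino_keto"`, `"weak_strong"`.
#' @return A `grouping_scheme` object: a list with elements `name`,
#'   `low_symbol`, `high_symbol` and `nucleotide_map` (named character vector
#'   A/C/G/T -> "low"/"high").
#' @examples
#' grouping_scheme("purine_pyrimidine")
#' @seealso [pcmer_schemes()] for all three in canonical order.
#' @export
grouping_scheme <- function(name = c("purine_pyrimidine", "amino_keto",
                                     "weak_strong")) {
  name <- match.arg(name)
  .schemes[[name]]
}

#' @describeIn grouping_scheme All three schemes, in the fixed order
#'   purine_pyrimidine, amino_keto, weak_strong used throughout the package.
#' @export
pcmer_schemes <- function() .schemes

new_scheme <- function(name, low_symbol, high_symbol, low_nts, high_nts) {
  map <- c(stats::setNames(rep("low", 2L), low_nts),
           stats::setNames(rep("high", 2L), high_nts))
  structure(list(name = name, low_symbol = low_symbol,
                 high_symbol = high_symbol,
                 nucleotide_map = map[c("A", "C", "G", "T")]),
            class = "grouping_scheme")
}

# canonical order: purine_pyrimidine, amino_keto, weak_strong
.schemes <- list(
  purine_pyrimidine = new_scheme("purine_pyrimidine", "R", "Y",
                                 c("A", "G"), c("C", "T")),
  amino_keto        = new_scheme("amino_keto", "M", "K",
                                 c("A", "C"), c("G", "T")),
  weak_strong       = new_scheme("weak_strong", "S", "W",
                                 c("C", "G"), c("A", "T"))
)

.scheme_names <- names(.schemes)

# high/low membership as a 0/1 bit per nucleotide, indexed by the digit
# codes A=0, C=1, G=2, T=3 used by the FCGR encoder
.scheme_bits <- local({
  nts <- c("A", "C", "G", "T")
  sapply(.schemes, function(s) as.integer(s$nucleotide_map[nts] == "high"))
})

#' @export
print.grouping_scheme <- function(x, ...) {
  low <- names(x$nucleotide_map)[x$nucleotide_map == "low"]
  high <- names(x$nucleotide_map)[x$nucleotide_map == "high"]
  cat(sprintf("Grouping scheme '%s': {%s} -> %s (low, endpoint 0); {%s} -> %s (high, endpoint 2^k)\n",
              x$name, paste(low, collapse = ","), x$low_symbol,
              paste(high, collapse = ","), x$high_symbol))
  invisible(x)
}

# The break sentinel emitted for ambiguous (non-ACGT) residues by
# transform_sequence(); the walk resets when it is met.
.break_sentinel <- "x"
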