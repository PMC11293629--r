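#' Define a sequence class as an order-1 Markov chain
#'
#' Synthetic stand-in for a taxon: sequences of a class are drawn from a
#' first-order Markov chain over A, C, G, T. Distinct transition matrices
#' give the classes distinct k-mer spectra for every k >= 2, so class
#' separability can be dialled from trivial to impossible by moving the
#' matrices toward each other.
#'
#' @param label class label string.
#' @param transition 4x4 row-stochastic matrix over A, C, G, T (rows sum to
#'   1 within 1e-9, entries non-negative).
#' @param initial initial base distribution (4 probabilities summing to 1);
#'   default uniform.
#' @return a `class_model` object.
#' @export
class_model <- function(label, transition, initial = rep(0.25, 4)) {
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(4L, 4L)))
    stop("'transition' must be a 4x4 matrix")
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9))
    stop("'transition' must be row-stochastic (rows summing to 1, entries >= 0)")
  if (length(initial) != 4L || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-9)
    stop("'initial' must be 4 probabilities summing to 1")
  dimnames(transition) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  structure(list(label = as.character(label), transition = transition,
                 initial = as.numeric(initial)),
            class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("Markov class model '%s'\n", x$label))
  print(round(x$transition, 3))
  invisible(x)
}

# draw n Markov sequences of the given length from one model (vectorized
# across sequences, sequential across positions)
draw_markov <- function(model, n, length) {
  nts <- c("A", "C", "G", "T")
  cum_init <- cumsum(model$initial)
  cum_tr <- t(apply(model$transition, 1L, cumsum))
  states <- matrix(0L, nrow = n, ncol = length)
  states[, 1L] <- findInterval(stats::runif(n), cum_init,
                               rightmost.closed = TRUE) + 1L
  if (length > 1L) {
    for (j in 2:length) {
      u <- stats::runif(n)
      prev <- states[, j - 1L]
      nxt <- integer(n)
      for (s in 1:4) {
        at <- prev == s
        if (any(at))
          nxt[at] <- findInterval(u[at], cum_tr[s, ],
                                  rightmost.closed = TRUE) + 1L
      }
      states[, j] <- nxt
    }
  }
  apply(states, 1L, function(row) paste(nts[row], collapse = ""))
}

#' Generate a labeled multi-class Markov sequence dataset
#'
#' Draws `n_per_class` sequences of the given length from each class model.
#' Fully reproducible from `seed`.
#'
#' @param models list of [class_model()] objects with distinct labels.
#' @param n_per_class sequences per class.
#' @param length sequence length (>= 1).
#' @param seed integer seed.
#' @param level_name tag stored on the dataset (default `"synthetic"`).
#' @return a `labeled_dataset`; record ids are `<label>_<i>`.
#' @export
generate_class_dataset <- function(models, n_per_class, length, seed,
                                   level_name = "synthetic") {
  stopifnot(length >= 1L, n_per_class >= 1L)
  models <- lapply(models, function(m) {
    if (!inherits(m, "class_model")) stop("'models' must be class_model objects")
    m
  })
  labels <- vapply(models, function(m) m$label, character(1L))
  if (anyDuplicated(labels)) stop("class labels must be distinct")
  with_seed(seed, {
    parts <- lapply(models, function(m) {
      data.frame(id = paste0(m$label, "_", seq_len(n_per_class)),
                 seq = draw_markov(m, n_per_class, length),
                 label = m$label, stringsAsFactors = FALSE)
    })
  })
  all <- do.call(rbind, parts)
  labeled_dataset(all[, c("id", "seq")], all$label, level_name)
}

#' Point-mutate a sequence
#'
#' Substitutes each position with probability `sub_rate` (uniformly over
#' the three alternative bases), deletes each position with probability
#' `indel_rate / 2`, and inserts a uniform random base after each position
#' with probability `indel_rate / 2`. Reproducible from `seed`.
#'
#' @param seq a nucleotide string over A/C/G/T.
#' @param sub_rate substitution probability per position, in `[0, 1]`.
#' @param indel_rate total insertion+deletion probability per position, in
#'   `[0, 1]` (default 0, which keeps sequence length fixed).
#' @param seed integer seed.
#' @return the mutated sequence string.
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate = 0, seed = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L,
            sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1)
  nts <- c("A", "C", "G", "T")
  d <- seq_digits(normalize_residues(seq))
  if (anyNA(d)) stop("mutate_sequence() requires an unambiguous A/C/G/T sequence")
  n <- length(d)
  with_seed(seed, {
    sub_at <- stats::runif(n) < sub_rate
    if (any(sub_at)) {
      offset <- sample.int(3L, sum(sub_at), replace = TRUE)
      d[sub_at] <- (d[sub_at] + offset) %% 4L
    }
    if (indel_rate > 0) {
      del_at <- stats::runif(n) < indel_rate / 2
      ins_at <- stats::runif(n) < indel_rate / 2
      ins_base <- sample.int(4L, n, replace = TRUE) - 1L
      pieces <- character(n)
      keep <- !del_at
      pieces[keep] <- nts[d[keep] + 1L]
      pieces[ins_at] <- paste0(pieces[ins_at], nts[ins_base[ins_at] + 1L])
      out <- paste(pieces, collapse = "")
    } else {
      out <- paste(nts[d + 1L], collapse = "")
    }
  })
  out
}

#' Build a divergence series from one ancestor
#'
#' Emulates graded evolutionary divergence: for each substitution rate,
#' `n_replicates` independently mutated copies of the ancestor are
#' generated (via [mutate_sequence()]). Labels are the rate bins
#' (`rate_<r>`); the ancestor itself is included with label `"ancestor"`.
#' The known rates serve as ground-truth divergence for distance
#' correlation tests.
#'
#' @param ancestor ancestor sequence string.
#' @param rates substitution rates in `[0, 1]`, sorted ascending.
#' @param n_replicates mutated copies per rate.
#' @param indel_rate passed to [mutate_sequence()] (default 0).
#' @param seed integer seed.
#' @return a `labeled_dataset` with `1 + length(rates) * n_replicates`
#'   records; the rates are stored in `attr(, "rates")` per record.
#' @export
make_divergence_series <- function(ancestor, rates, n_replicates,
                                   indel_rate = 0, seed = 1L) {
  stopifnot(is.character(ancestor), length(ancestor) == 1L,
            all(rates >= 0), all(rates <= 1), n_replicates >= 1L)
  if (is.unsorted(rates))
    stop("'rates' must be sorted ascending")
  ids <- "ancestor"
  seqs <- normalize_residues(ancestor)
  labels <- "ancestor"
  rate_of <- 0
  counter <- 0L
  for (r in rates) {
    for (rep in seq_len(n_replicates)) {
      counter <- counter + 1L
      ids <- c(ids, sprintf("rate_%g_rep%d", r, rep))
      seqs <- c(seqs, mutate_sequence(ancestor, sub_rate = r,
                                      indel_rate = indel_rate,
                                      seed = seed + counter))
      labels <- c(labels, sprintf("rate_%g", r))
      rate_of <- c(rate_of, r)
    }
  }
  ds <- labeled_dataset(data.frame(id = ids, seq = seqs,
                                   stringsAsFactors = FALSE),
                        labels, level_name = "divergence")
  attr(ds, "rates") <- rate_of
  ds
}

#' Random class models of controllable similarity
#'
#' Convenience generator for simulation studies: draws `n_classes`
#' transition matrices as `(1 - separation) * shared + separation * own`,
#' where `shared` and each `own` matrix have Dirichlet(1) rows. At
#' `separation = 0` all classes coincide (classification is impossible);
#' at 1 they are independent draws.
#'
#' @param n_classes number of classes.
#' @param separation mixing weight in `[0, 1]`.
#' @param seed integer seed.
#' @param labels class labels (default `class_1 ...`).
#' @return list of [class_model()] objects.
#' @export
random_class_models <- function(n_classes, separation = 1, seed = 1L,
                                labels = paste0("class_", seq_len(n_classes))) {
  stopifnot(n_classes >= 1L, separation >= 0, separation <= 1,
            length(labels) == n_classes)
  rand_stochastic <- function() {
    m <- matrix(stats::rexp(16L), 4L, 4L)
    m / rowSums(m)
  }
  with_seed(seed, {
    shared <- rand_stochastic()
    models <- lapply(seq_len(n_classes), function(i)
      class_model(labels[i],
                  (1 - separation) * shared + separation * rand_stochastic()))
  })
  models
}
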