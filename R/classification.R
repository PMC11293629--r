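#' Specify one of the eight basic classifiers
#'
#' The supervised layer on top of PC-mer features deliberately uses simple,
#' well-understood classifiers. The eight configurations and their fixed
#' hyperparameters are:
#'
#' * `logistic_regression` — L2-penalized, one-vs-rest, regularization
#'   strength C = 1, convergence tolerance 1e-4 (fit via [glmnet::glmnet]
#'   ridge binomial models, one per class, at `lambda = 1/(n * C)`).
#' * `decision_tree` — CART with Gini impurity ([rpart::rpart]).
#' * `gaussian_nb` — Gaussian naive Bayes ([e1071::naiveBayes]).
#' * `lda` — linear discriminant analysis ([MASS::lda]).
#' * `mlp` — multi-layer perceptron, one 100-neuron hidden layer, L2 weight
#'   decay 1e-4, at most 200 optimization passes ([nnet::nnet]).
#' * `linear_svc` — support vector classifier with a linear kernel, cost 1
#'   ([e1071::svm]).
#' * `nearest_centroid_mean` — assign to the nearest class mean (Euclidean).
#' * `nearest_centroid_median` — assign to the nearest per-feature class
#'   median (Manhattan).
#'
#' Hyperparameters not listed stay at the backing library's defaults.
#'
#' @param name classifier name (see above).
#' @param ... hyperparameter overrides (e.g. `C = 10` for
#'   `logistic_regression`).
#' @return a `classifier_spec` object.
#' @export
classifier_spec <- function(name = classifier_names(), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    logistic_regression = list(C = 1, tol = 1e-4),
    decision_tree = list(),
    gaussian_nb = list(),
    lda = list(),
    mlp = list(hidden = 100L, decay = 1e-4, maxit = 200L),
    linear_svc = list(cost = 1),
    nearest_centroid_mean = list(),
    nearest_centroid_median = list())
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", name, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  structure(list(name = name, hyperparameters = defaults),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
classifier_names <- function() {
  c("logistic_regression", "decision_tree", "gaussian_nb", "lda", "mlp",
    "linear_svc", "nearest_centroid_mean", "nearest_centroid_median")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters))
    paste(names(x$hyperparameters), unlist(x$hyperparameters),
          sep = " = ", collapse = ", ")
  else "library defaults"
  cat(sprintf("Classifier '%s' (%s)\n", x$name, hp))
  invisible(x)
}

#' Build the PC-mer feature matrix of a labeled dataset
#'
#' Encodes every record with [encode_pcmer()] and stacks the concatenated
#' feature vectors, row order matching record order.
#'
#' @param dataset a `labeled_dataset`.
#' @param k word length.
#' @param mode counting mode, `"all_positions"` (default) or `"kmer_only"`.
#' @param normalize divide each profile by its counted positions.
#' @return list with `features` (n x `3*2^k` numeric matrix, rownames =
#'   record ids) and `labels` (character vector).
#' @export
build_feature_matrix <- function(dataset, k,
                                 mode = c("all_positions", "kmer_only"),
                                 normalize = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  mode <- match.arg(mode)
  check_k(k, max = 24L)
  rows <- lapply(seq_len(nrow(dataset$records)), function(i) {
    id <- dataset$records$id[i]
    tryCatch({
      p <- encode_pcmer(dataset$records$seq[i], k = k, mode = mode)
      if (normalize) p <- normalize_profile(p)
      feature_vector(p)
    }, error = function(e)
      stop("encoding failed for record '", id, "': ", conditionMessage(e),
           call. = FALSE))
  })
  x <- do.call(rbind, rows)
  rownames(x) <- dataset$records$id
  list(features = x, labels = dataset$labels)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# drop feature columns whose pooled within-class standard deviation is ~0
# (needed by covariance-based fits: lda)
informative_columns <- function(x, y, tol = 1e-10) {
  centered <- x - rowsum(x, y)[y, , drop = FALSE] / as.vector(table(y))[y]
  which(apply(centered, 2L, stats::sd) > tol)
}

fit_model <- function(spec, x, y, seed = 1L) {
  hp <- spec$hyperparameters
  lv <- levels(y)
  keep <- NULL
  fit <- switch(spec$name,
    logistic_regression = {
      lambda <- 1 / (nrow(x) * hp$C)
      lapply(lv, function(cl)
        glmnet::glmnet(x, factor(y == cl, levels = c(FALSE, TRUE)),
                       family = "binomial", alpha = 0, lambda = lambda,
                       standardize = FALSE, thresh = hp$tol))
    },
    decision_tree = {
      df <- as.data.frame(x)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "gini"))
    },
    gaussian_nb = {
      keep <- which(apply(x, 2L, stats::sd) > 0)
      e1071::naiveBayes(x[, keep, drop = FALSE], y)
    },
    lda = {
      keep <- informative_columns(x, y)
      # count blocks each sum to positions_counted, so exact collinearity
      # is structural; MASS::lda warns but handles it
      withCallingHandlers(
        MASS::lda(x[, keep, drop = FALSE], grouping = y),
        warning = function(w) {
          if (grepl("collinear", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    },
    mlp = with_seed(seed,
      nnet::nnet(x, nnet::class.ind(y), size = hp$hidden, softmax = TRUE,
                 decay = hp$decay, maxit = hp$maxit, MaxNWts = 1e7,
                 trace = FALSE)),
    linear_svc = e1071::svm(x, y, kernel = "linear", cost = hp$cost,
                            scale = FALSE),
    nearest_centroid_mean =
      rowsum(x, y) / as.vector(table(y)),
    nearest_centroid_median =
      do.call(rbind, lapply(split(as.data.frame(x), y), function(d)
        apply(d, 2L, stats::median))),
    stop("unknown classifier: ", spec$name))
  structure(list(spec = spec, fit = fit, levels = lv, keep = keep),
            class = "pcmer_model")
}

predict_model <- function(model, x) {
  lv <- model$levels
  if (!is.null(model$keep)) x <- x[, model$keep, drop = FALSE]
  pred <- switch(model$spec$name,
    logistic_regression = {
      scores <- vapply(model$fit, function(f)
        as.numeric(stats::predict(f, newx = x, type = "response")),
        numeric(nrow(x)))
      if (nrow(x) == 1L) scores <- matrix(scores, nrow = 1L)
      lv[max.col(scores, ties.method = "first")]
    },
    decision_tree =
      as.character(stats::predict(model$fit, as.data.frame(x),
                                  type = "class")),
    gaussian_nb = as.character(stats::predict(model$fit, x)),
    lda = as.character(stats::predict(model$fit, x)$class),
    mlp = {
      scores <- stats::predict(model$fit, x)  # columns in training level order
      lv[max.col(scores, ties.method = "first")]
    },
    linear_svc = as.character(stats::predict(model$fit, x)),
    nearest_centroid_mean = {
      cent <- model$fit
      d <- vapply(seq_len(nrow(cent)), function(j)
        rowSums((x - matrix(cent[j, ], nrow(x), ncol(x), byrow = TRUE))^2),
        numeric(nrow(x)))
      if (nrow(x) == 1L) d <- matrix(d, nrow = 1L)
      rownames(cent)[max.col(-d, ties.method = "first")]
    },
    nearest_centroid_median = {
      cent <- model$fit
      d <- vapply(seq_len(nrow(cent)), function(j)
        rowSums(abs(x - matrix(cent[j, ], nrow(x), ncol(x), byrow = TRUE))),
        numeric(nrow(x)))
      if (nrow(x) == 1L) d <- matrix(d, nrow = 1L)
      rownames(cent)[max.col(-d, ties.method = "first")]
    })
  factor(pred, levels = lv)
}

# per-class precision/recall/F1 from a truth x prediction confusion matrix
confusion_metrics <- function(cm) {
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  true_tot <- rowSums(cm)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  recall <- ifelse(true_tot > 0, tp / true_tot, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  present <- true_tot > 0
  list(
    accuracy = sum(tp) / sum(cm),
    precision_macro = mean(precision[present]),
    recall_macro = mean(recall[present]),
    f1_macro = mean(f1[present]),
    precision_weighted = sum(precision[present] * true_tot[present]) /
      sum(true_tot),
    recall_weighted = sum(recall[present] * true_tot[present]) /
      sum(true_tot),
    f1_weighted = sum(f1[present] * true_tot[present]) / sum(true_tot))
}

#' Stratified k-fold cross-validation of a classifier on feature rows
#'
#' Splits the rows into stratified folds (each class spread as evenly as
#' possible), fits the classifier on the training split only, predicts the
#' held-out fold, and reports accuracy, precision, recall and F1 — macro
#' averages as the primary numbers, weighted averages alongside — per fold
#' and averaged over folds, plus the confusion matrix summed over folds.
#' Fold assignment and any stochastic fitting are driven entirely by
#' `seed`, so a rerun with the same seed reproduces the report.
#'
#' @param features numeric matrix, one row per sequence.
#' @param labels class label per row (at least two classes, each with at
#'   least two members).
#' @param spec a [classifier_spec()] (or classifier name).
#' @param n_folds number of folds (default 10); lowered with a warning when
#'   the smallest class has fewer members.
#' @param seed integer seed for fold assignment and stochastic fits.
#' @return a `cv_report`: list with `classifier`, `n_folds`, `seed`, `n`,
#'   `classes`, `per_fold` (data.frame of fold metrics), `mean_metrics`
#'   (arithmetic mean over folds), `accuracy_pooled` (from the summed
#'   confusion matrix) and `confusion` (truth x prediction).
#' @export
cross_validate <- function(features, labels, spec, n_folds = 10L,
                           seed = 1L) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(spec, "classifier_spec"), is.matrix(features),
            nrow(features) == length(labels))
  y <- factor(labels)
  if (nlevels(y) < 2L)
    stop("cross-validation needs at least two classes")
  class_n <- table(y)
  if (min(class_n) < 2L)
    stop("every class needs at least two members; too small: ",
         paste(names(class_n)[class_n < 2L], collapse = ", "))
  if (min(class_n) < n_folds) {
    n_folds <- as.integer(min(class_n))
    warning("smallest class has ", min(class_n),
            " members; lowering n_folds to ", n_folds)
  }
  n <- nrow(features)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  cm_total <- matrix(0L, nlevels(y), nlevels(y),
                     dimnames = list(truth = levels(y), pred = levels(y)))
  fold_rows <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- folds == f
    model <- fit_model(spec, features[!test, , drop = FALSE],
                       droplevels(y[!test]), seed = seed + f)
    pred <- predict_model(model, features[test, , drop = FALSE])
    pred <- factor(as.character(pred), levels = levels(y))
    cm <- table(truth = y[test], pred = pred)
    cm_total <- cm_total + cm
    fold_rows[[f]] <- c(fold = f, unlist(confusion_metrics(cm)))
  }
  per_fold <- as.data.frame(do.call(rbind, fold_rows))
  means <- colMeans(per_fold[, -1L, drop = FALSE])
  structure(list(classifier = spec$name, spec = spec,
                 n_folds = n_folds, seed = seed, n = n,
                 classes = levels(y), per_fold = per_fold,
                 mean_metrics = means,
                 accuracy_pooled = sum(diag(cm_total)) / sum(cm_total),
                 confusion = cm_total),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV of '%s' on %d sequences, %d classes (seed %d)\n",
              x$n_folds, x$classifier, x$n, length(x$classes), x$seed))
  m <- x$mean_metrics
  cat(sprintf("  accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f (macro means over folds)\n",
              m[["accuracy"]], m[["precision_macro"]], m[["recall_macro"]],
              m[["f1_macro"]]))
  cat(sprintf("  pooled accuracy from summed confusion matrix: %.4f\n",
              x$accuracy_pooled))
  invisible(x)
}

#' Cross-validate over a grid of k values and classifiers
#'
#' Encodes the dataset once per `k` and runs [cross_validate()] for every
#' (k, classifier) pair, in k-major order.
#'
#' @param dataset a `labeled_dataset`.
#' @param k_values integer vector of word lengths.
#' @param specs list of [classifier_spec()] objects (or classifier names).
#' @inheritParams cross_validate
#' @inheritParams build_feature_matrix
#' @return list of `cv_report` objects, each with `$k` set; names
#'   `k<k>_<classifier>`.
#' @export
sweep_classifiers <- function(dataset, k_values, specs, n_folds = 10L,
                              seed = 1L, mode = "all_positions") {
  specs <- lapply(specs, function(s)
    if (is.character(s)) classifier_spec(s) else s)
  reports <- list()
  for (k in k_values) {
    fm <- build_feature_matrix(dataset, k = k, mode = mode)
    for (spec in specs) {
      rep <- cross_validate(fm$features, fm$labels, spec,
                            n_folds = n_folds, seed = seed)
      rep$k <- as.integer(k)
      reports[[paste0("k", k, "_", spec$name)]] <- rep
    }
  }
  reports
}

#' Serialize a CV report to JSON
#'
#' @param report a `cv_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  out <- list(classifier = report$classifier, k = report$k,
              n_folds = report$n_folds, seed = report$seed, n = report$n,
              classes = report$classes,
              mean_metrics = as.list(report$mean_metrics),
              accuracy_pooled = report$accuracy_pooled,
              per_fold = report$per_fold,
              confusion = as.data.frame.matrix(report$confusion))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
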