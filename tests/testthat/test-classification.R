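two_block_dataset <- function(n_per_class = 12, length = 200, seed = 21) {
  # disjoint composition: one class pure AT-rich walk, one pure GC-rich
  m1 <- class_model("at", matrix(c(.45, .05, .05, .45,
                                   .45, .05, .05, .45,
                                   .45, .05, .05, .45,
                                   .45, .05, .05, .45), 4, byrow = TRUE))
  m2 <- class_model("gc", matrix(c(.05, .45, .45, .05,
                                   .05, .45, .45, .05,
                                   .05, .45, .45, .05,
                                   .05, .45, .45, .05), 4, byrow = TRUE))
  generate_class_dataset(list(m1, m2), n_per_class, length, seed)
}

test_that("build_feature_matrix stacks profiles in record order, deterministically", {
  ds <- two_block_dataset(5, 100)
  fm <- build_feature_matrix(ds, k = 3)
  expect_equal(dim(fm$features), c(10L, 24L))  # 3 * 2^3
  expect_equal(rownames(fm$features), ds$records$id)
  expect_equal(fm$labels, ds$labels)
  expect_equal(unname(fm$features[4, ]),
               unname(feature_vector(encode_pcmer(ds$records$seq[4], 3))))
  expect_identical(fm, build_feature_matrix(ds, k = 3))

  # encoding failures carry the record id
  bad <- ds
  bad$records$seq[2] <- ""
  expect_error(build_feature_matrix(bad, k = 3), bad$records$id[2])
})

test_that("classifier specs carry the documented default hyperparameters", {
  expect_equal(classifier_spec("logistic_regression")$hyperparameters,
               list(C = 1, tol = 1e-4))
  expect_equal(classifier_spec("mlp")$hyperparameters,
               list(hidden = 100L, decay = 1e-4, maxit = 200L))
  expect_equal(classifier_spec("linear_svc")$hyperparameters,
               list(cost = 1))
  expect_equal(classifier_spec("mlp", hidden = 5L)$hyperparameters$hidden, 5L)
  expect_error(classifier_spec("lda", gamma = 2), "unknown hyperparameter")
  expect_error(classifier_spec("boosted_stumps"))
  expect_length(classifier_names(), 8L)
})

test_that("logistic regression separates disjoint-composition classes perfectly", {
  ds <- two_block_dataset(12, 200)
  fm <- build_feature_matrix(ds, k = 4)
  rep <- cross_validate(fm$features, fm$labels, "logistic_regression",
                        n_folds = 4, seed = 11)
  expect_equal(rep$mean_metrics[["accuracy"]], 1)
  expect_equal(rep$accuracy_pooled, 1)
  expect_equal(unname(rep$confusion["at", "gc"]), 0L)
})

test_that("all eight classifiers produce valid CV reports on an easy problem", {
  # large enough that rpart's minsplit default (20) can act on each fold
  ds <- two_block_dataset(15, 150)
  fm <- build_feature_matrix(ds, k = 3)
  for (nm in classifier_names()) {
    spec <- if (nm == "mlp") classifier_spec("mlp", hidden = 8L)
            else classifier_spec(nm)
    rep <- cross_validate(fm$features, fm$labels, spec, n_folds = 4,
                          seed = 5)
    expect_s3_class(rep, "cv_report")
    expect_equal(nrow(rep$per_fold), 4L)
    expect_equal(sum(rep$confusion), 30L)
    for (m in c("accuracy", "precision_macro", "recall_macro", "f1_macro",
                "precision_weighted", "recall_weighted", "f1_weighted")) {
      expect_gte(rep$mean_metrics[[m]], 0)
      expect_lte(rep$mean_metrics[[m]], 1)
    }
    # composition is fully disjoint: everything should score highly
    expect_gte(rep$mean_metrics[["accuracy"]], 0.9)
  }
})

test_that("CV folds and reports are reproducible from the seed", {
  # weakly separated classes, so fold composition is visible in the metrics
  models <- random_class_models(2, separation = 0.15, seed = 51)
  ds <- generate_class_dataset(models, n_per_class = 15, length = 120,
                               seed = 52)
  fm <- build_feature_matrix(ds, k = 3)
  r1 <- cross_validate(fm$features, fm$labels, "nearest_centroid_mean",
                       n_folds = 5, seed = 42)
  r2 <- cross_validate(fm$features, fm$labels, "nearest_centroid_mean",
                       n_folds = 5, seed = 42)
  r1$spec <- r2$spec <- NULL
  expect_identical(r1[names(r1) != "confusion"], r2[names(r2) != "confusion"])
  expect_equal(r1$confusion, r2$confusion)
  r3 <- cross_validate(fm$features, fm$labels, "nearest_centroid_mean",
                       n_folds = 5, seed = 43)
  expect_false(identical(r1$per_fold, r3$per_fold))
})

test_that("accuracy from the summed confusion matrix equals pooled accuracy", {
  ds <- two_block_dataset(9, 100, seed = 31)
  fm <- build_feature_matrix(ds, k = 2)
  rep <- cross_validate(fm$features, fm$labels, "gaussian_nb",
                        n_folds = 3, seed = 2)
  expect_equal(sum(diag(rep$confusion)) / sum(rep$confusion),
               rep$accuracy_pooled, tolerance = 1e-12)
  # confusion row sums equal per-class test counts
  expect_equal(unname(rowSums(rep$confusion)),
               unname(as.vector(table(fm$labels))))
})

test_that("cross_validate guards degenerate inputs and lowers fold counts", {
  ds <- two_block_dataset(4, 80, seed = 13)
  fm <- build_feature_matrix(ds, k = 2)
  expect_error(cross_validate(fm$features, rep("one", 8), "lda"),
               "two classes")
  expect_warning(rep <- cross_validate(fm$features, fm$labels, "lda",
                                       n_folds = 10, seed = 1),
                 "lowering n_folds")
  expect_equal(rep$n_folds, 4L)
  expect_error(cross_validate(fm$features, c("a", rep("b", 7)), "lda"),
               "at least two members")
})

test_that("permuted labels give chance-level accuracy (no leakage)", {
  models <- random_class_models(3, separation = 1, seed = 61)
  ds <- generate_class_dataset(models, n_per_class = 20, length = 200,
                               seed = 62)
  fm <- build_feature_matrix(ds, k = 4)
  set.seed(63)
  yperm <- sample(fm$labels)
  rep <- cross_validate(fm$features, yperm, "logistic_regression",
                        n_folds = 5, seed = 64)
  n <- length(yperm)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(rep$accuracy_pooled - 1 / 3), 3 * se + 1e-9)
})

test_that("sweep_classifiers yields one deterministic report per (k, spec)", {
  ds <- two_block_dataset(6, 100, seed = 71)
  reports <- sweep_classifiers(ds, k_values = c(2, 3),
                               specs = list("nearest_centroid_mean",
                                            "decision_tree"),
                               n_folds = 3, seed = 5)
  expect_length(reports, 4L)
  expect_equal(names(reports),
               c("k2_nearest_centroid_mean", "k2_decision_tree",
                 "k3_nearest_centroid_mean", "k3_decision_tree"))
  expect_equal(vapply(reports, `[[`, integer(1), "k"),
               c(k2_nearest_centroid_mean = 2L, k2_decision_tree = 2L,
                 k3_nearest_centroid_mean = 3L, k3_decision_tree = 3L))
  reports2 <- sweep_classifiers(ds, k_values = c(2, 3),
                                specs = list("nearest_centroid_mean",
                                             "decision_tree"),
                                n_folds = 3, seed = 5)
  expect_equal(vapply(reports, function(r) r$mean_metrics[["accuracy"]],
                      numeric(1)),
               vapply(reports2, function(r) r$mean_metrics[["accuracy"]],
                      numeric(1)))
})

test_that("CV reports serialize to JSON", {
  ds <- two_block_dataset(6, 80, seed = 81)
  fm <- build_feature_matrix(ds, k = 2)
  rep <- cross_validate(fm$features, fm$labels, "nearest_centroid_median",
                        n_folds = 3, seed = 1)
  rep$k <- 2L
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$classifier, "nearest_centroid_median")
  expect_equal(back$mean_metrics$accuracy, rep$mean_metrics[["accuracy"]])
})
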