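test_that("stratified folds partition the data and preserve class balance", {
  labels <- rep(1:7, each = 10)
  folds <- stratified_kfold(labels, k = 5, seed = 3)
  tests <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(tests)), seq_along(labels))
  expect_true(all(vapply(tests, length, integer(1)) == 14L))
  for (f in folds) {
    expect_true(all(table(labels[f$test]) == 2))
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_identical(stratified_kfold(labels, 5, seed = 3),
                   stratified_kfold(labels, 5, seed = 3))
  expect_false(identical(stratified_kfold(labels, 5, seed = 3),
                         stratified_kfold(labels, 5, seed = 4)))

  # unbalanced classes: per-fold class counts within 1 of n_c / k
  lab2 <- rep(1:3, times = c(23, 11, 7))
  for (f in stratified_kfold(lab2, 5, seed = 1)) {
    tab <- table(factor(lab2[f$test], levels = 1:3))
    expect_true(all(abs(tab - c(23, 11, 7) / 5) <= 1))
  }
  expect_error(stratified_kfold(c(1, 1, 1, 2), k = 2),
               class = "emgpipe_data_error")
})

test_that("confusion-matrix metrics match hand computation", {
  cm <- matrix(c(8, 2, 1, 9), nrow = 2, byrow = TRUE)
  m <- precision_recall_f1_acc(cm, 1)
  expect_equal(m[["precision"]], 8 / 9)
  expect_equal(m[["recall"]], 0.8)
  expect_equal(m[["f1"]], 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  expect_equal(m[["accuracy"]], m[["recall"]])
  expect_equal(overall_accuracy(cm), 0.85)

  diagcm <- diag(c(5, 3, 7))
  for (cl in 1:3)
    expect_equal(precision_recall_f1_acc(diagcm, cl),
                 c(precision = 1, recall = 1, f1 = 1, accuracy = 1))
  expect_equal(overall_accuracy(diagcm), 1)
  off <- matrix(1, 3, 3) - diag(1, 3)
  expect_equal(overall_accuracy(off), 0)

  # class never predicted and never present: zero-division convention
  cm0 <- diag(c(4, 5, 0))
  expect_warning(m0 <- precision_recall_f1_acc(cm0, 3), "zero division")
  expect_equal(unname(m0), rep(0, 4))
})

test_that("micro accuracy is invariant under simultaneous relabeling", {
  set.seed(5)
  cm <- matrix(rpois(49, 4), 7, 7)
  perm <- sample(7)
  expect_equal(overall_accuracy(cm), overall_accuracy(cm[perm, perm]))
})

test_that("one-vs-rest AUC follows the Mann-Whitney contract", {
  # perfect separation
  expect_identical(roc_auc_ovr(c(5, 6, 1, 2), c(1, 1, 2, 2), 1), 1)
  # all ties
  expect_identical(roc_auc_ovr(rep(0.3, 10), rep(1:2, 5), 1), 0.5)
  # hand-enumerated pairs
  expect_identical(roc_auc_ovr(c(0.9, 0.8, 0.7, 0.1), c(1, 2, 1, 2), 1), 0.75)
  expect_error(roc_auc_ovr(c(1, 2), c(1, 1), 1), class = "emgpipe_auc_error")
  expect_error(roc_auc_ovr(c(1, NA), c(1, 2), 1), class = "emgpipe_data_error")
})

test_that("benchmark pools folds correctly and is deterministic", {
  fm <- tiny_features(8L, seed = 21L)
  bm <- run_benchmark(fm, models = default_model_specs(c("LR", "RF")),
                      k = 4, seed = 6)
  for (r in bm) {
    expect_null(r$error)
    expect_identical(sum(r$confusion), as.numeric(length(fm$labels)))
    # F1 harmonic-mean identity on every emitted row (pre-rounding)
    pc <- r$per_class
    hm <- 2 * pc$precision * pc$recall / (pc$precision + pc$recall)
    expect_equal(pc$f1, hm, tolerance = 1e-10)
    expect_true(all(pc$auc >= 0 & pc$auc <= 100))
    expect_equal(r$overall$accuracy,
                 100 * sum(diag(r$confusion)) / sum(r$confusion))
  }
  bm2 <- run_benchmark(fm, models = default_model_specs(c("LR", "RF")),
                       k = 4, seed = 6)
  expect_identical(bm$RF$per_class, bm2$RF$per_class)
  expect_identical(bm$LR$confusion, bm2$LR$confusion)
})

test_that("chance-level data yields chance-level scores", {
  rec <- generate_recording(synth_config(
    class_counts = rep(25L, 7), activation_profile = flat_profile(),
    seed = 19L))
  fm <- extract_features(segment_recording(rec))
  bm <- run_benchmark(fm, models = default_model_specs("kNN"), k = 5,
                      seed = 2)
  expect_lt(abs(bm$kNN$overall$accuracy - 100 / 7), 8)
  expect_lt(abs(bm$kNN$overall$auc - 50), 6)
})

test_that("model ranking on armband-like data echoes RF/kNN over LR", {
  # soft ordering at the generator's stated (moderate-noise) world, majority
  # over seeds; see the methods vignette for what this does NOT establish
  wins <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    rec <- generate_recording(synth_config(class_counts = rep(12L, 7),
                                           seed = 300 + s))
    fm <- extract_features(segment_recording(rec))
    bm <- run_benchmark(fm, models = default_model_specs(c("LR", "kNN", "RF")),
                        k = 3, seed = s)
    acc <- vapply(bm, function(r) r$overall$accuracy, numeric(1))
    if (acc[["RF"]] >= acc[["LR"]] && acc[["kNN"]] >= acc[["LR"]])
      wins <- wins + 1L
  }
  expect_gt(wins, n_seeds / 2)
})

test_that("per-model failures do not abort the benchmark", {
  fm <- tiny_features(6L, seed = 23L)
  broken <- model_spec("kNN", hyperparams = list(k = 100000L))
  bm <- run_benchmark(fm, models = list(broken, model_spec("LR")),
                      k = 3, seed = 1)
  expect_false(is.null(bm$kNN$error))
  expect_null(bm$LR$error)
})

test_that("emitted tables have the documented shape and rounding", {
  fm <- tiny_features(6L, seed = 27L)
  bm <- run_benchmark(fm, models = default_model_specs(c("RF", "LR")),
                      k = 3, seed = 4)
  dir <- file.path(tempdir(), "tables")
  emit_tables(bm, dir)
  tab <- read.csv(file.path(dir, "table_rf.csv"), check.names = FALSE)
  expect_identical(tab$Metric,
                   c("Precision", "Recall", "F1-score", "Accuracy", "AUC"))
  expect_identical(colnames(tab)[-1], paste("Class", 1:7))
  expect_true(all(tab[, -1] >= 0 & tab[, -1] <= 100))
  expect_true(all(abs(tab[, -1] * 100 - round(tab[, -1] * 100)) < 1e-9))
  ov <- read.csv(file.path(dir, "table_overall.csv"), check.names = FALSE)
  expect_identical(colnames(ov)[-1], c("RF", "LR"))
  expect_true(file.exists(file.path(dir, "table_overall.txt")))

  # a perfectly diagonal report prints 100.00 everywhere
  perfect <- bm$RF
  perfect$per_class[, c("precision", "recall", "f1", "accuracy", "auc")] <- 100
  m <- emgpipe:::report_table(perfect)
  expect_true(all(m == 100))
})

test_that("grid search selects within the documented grid", {
  fm <- tiny_features(5L, seed = 31L)
  bm <- run_benchmark(fm, models = default_model_specs("kNN"), k = 3,
                      seed = 2, grid_search = TRUE)
  expect_null(bm$kNN$error)
  expect_gte(bm$kNN$overall$accuracy, 50)
})
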