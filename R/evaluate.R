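#' Stratified k-fold cross-validation folds
#'
#' Partitions indices into `k` folds preserving per-class proportions: the
#' members of each class are shuffled (seeded) and dealt across folds, so
#' each fold's per-class count is within one sample of the class total
#' divided by `k`. Every index appears in exactly one test fold.
#'
#' @param labels integer class labels.
#' @param k number of folds (default 5).
#' @param seed integer RNG seed.
#' @return list of `k` elements, each with integer vectors `train`, `test`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2) stop_config("k must be >= 2")
  tab <- table(labels)
  if (any(tab < k))
    stop_data(sprintf("class %s has %d members, fewer than k = %d folds",
                      names(tab)[which(tab < k)[1]], min(tab), k))
  fold_of <- with_seed(seed, {
    fo <- integer(length(labels))
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      fo[idx] <- rep_len(seq_len(k), length(idx))
    }
    fo
  })
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Confusion matrix
#'
#' @param true,pred integer class labels.
#' @param n_class number of classes (default 7).
#' @return `n_class` x `n_class` count matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(true, pred, n_class = 7L) {
  cm <- table(factor(true, levels = seq_len(n_class)),
              factor(pred, levels = seq_len(n_class)))
  matrix(cm, n_class, n_class,
         dimnames = list(true = seq_len(n_class), pred = seq_len(n_class)))
}

#' Per-class precision, recall, F1 and accuracy from a confusion matrix
#'
#' One-vs-rest marginalization of the confusion matrix for one class:
#' precision = TP / (TP + FP), recall = TP / (TP + FN), F1 = harmonic mean
#' of the two. The per-class `accuracy` entry is reported as the recall,
#' mirroring the table convention of per-class score reports in which the
#' accuracy row equals the recall row; the genuinely distinct overall
#' accuracy is [overall_accuracy()]. Zero divisions yield 0 with a warning.
#'
#' @param cm confusion matrix (rows = true, columns = predicted).
#' @param class_id class to score.
#' @return named numeric vector `precision`, `recall`, `f1`, `accuracy`, on
#'   the 0-1 scale.
#' @export
precision_recall_f1_acc <- function(cm, class_id) {
  tp <- cm[class_id, class_id]
  fp <- sum(cm[, class_id]) - tp
  fn <- sum(cm[class_id, ]) - tp
  div0 <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("class %d: %s undefined (zero division), reported as 0",
                      class_id, what))
      0
    } else num / den
  }
  precision <- div0(tp, tp + fp, "precision")
  recall <- div0(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning(sprintf("class %d: F1 undefined (zero division), reported as 0",
                    class_id))
    0
  } else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1, accuracy = recall)
}

#' Overall (micro) accuracy
#'
#' @param cm confusion matrix.
#' @return `trace(cm) / sum(cm)`, the fraction of correctly predicted
#'   instances.
#' @export
overall_accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' One-vs-rest ROC-AUC
#'
#' Area under the ROC curve (true positive rate against false positive rate)
#' for one class against all others, computed as the Mann-Whitney statistic:
#' the fraction of (positive, negative) pairs in which the positive sample
#' scores higher, counting ties as 1/2. An AUC of 1 means perfect
#' separation; 0.5 means no discriminative power.
#'
#' @param scores per-segment scores: either a matrix with one column per
#'   class (column `class_id` is used) or a vector of scores for `class_id`.
#' @param labels integer class labels.
#' @param class_id positive class.
#' @return AUC on the 0-1 scale. Raises an error of class
#'   `emgpipe_auc_error` when the fold contains no positive or no negative
#'   samples for the class.
#' @export
roc_auc_ovr <- function(scores, labels, class_id) {
  s <- if (is.matrix(scores)) scores[, class_id] else scores
  if (any(!is.finite(s))) stop_data("AUC scores must be finite")
  pos <- labels == class_id
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop(structure(class = c("emgpipe_auc_error", "error", "condition"),
                   list(message = sprintf(
                     "AUC undefined for class %d: %d positives, %d negatives",
                     class_id, n1, n0), call = sys.call(-1))))
  r <- rank(s)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

engineer_fold <- function(x_train, x_test, retention) {
  zs <- zscore_fit(x_train)
  std_train <- zscore_transform(x_train, zs)
  fit <- pca_fit_transform(std_train, retention)
  list(train = fit$projected,
       test = pca_transform(zscore_transform(x_test, zs), fit),
       k = fit$k)
}

grid_search_spec <- function(spec, x, y, seed, n_class) {
  grid <- spec$grid %||% default_grid(spec$name)
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  if (nrow(combos) < 2) return(spec)
  inner <- stratified_kfold(y, k = 3L, seed = seed)
  acc <- vapply(seq_len(nrow(combos)), function(i) {
    hp <- as.list(combos[i, , drop = FALSE])
    if (spec$name == "RF" && !is.null(hp$mtry_factor)) {
      hp <- list(mtry = max(1L, floor(hp$mtry_factor * sqrt(ncol(x)))))
    }
    cand <- model_spec(spec$name, hyperparams = hp)
    mean(vapply(inner, function(fd) {
      m <- fit_classifier(cand, x[fd$train, , drop = FALSE], y[fd$train],
                          seed = seed, n_class = n_class)
      mean(predict_classifier(m, x[fd$test, , drop = FALSE])$class ==
             y[fd$test])
    }, numeric(1)))
  }, numeric(1))
  best <- as.list(combos[which.max(acc), , drop = FALSE])
  if (spec$name == "RF" && !is.null(best$mtry_factor))
    best <- list(mtry = max(1L, floor(best$mtry_factor * sqrt(ncol(x)))))
  model_spec(spec$name, hyperparams = best)
}

#' Cross-validated multi-classifier benchmark
#'
#' For every model: within each stratified fold, optionally fit the feature
#' engineering (z-score + PCA at `retention`) on the training rows only and
#' project the test rows with the stored parameters, fit the model, predict
#' the held-out rows, and accumulate a pooled confusion matrix and per-fold
#' one-vs-rest AUCs. Per-class precision/recall/F1 come from the pooled
#' confusion matrix (stable for small classes); AUC is averaged across
#' folds. `paper_mode = TRUE` instead fits z-score and PCA once on all rows
#' before splitting, replicating a global-fit protocol at the cost of
#' information leakage into the test folds.
#'
#' @param features an `emg_feature_matrix`, or a plain numeric matrix.
#' @param labels integer class labels; taken from `features` if missing.
#' @param models list of [model_spec()] objects
#'   (default [default_model_specs()]).
#' @param k number of folds (default 5).
#' @param seed integer seed driving fold assignment and model randomness.
#' @param retention PCA explained-variance target (default 0.999).
#' @param engineer apply z-score + PCA feature engineering (default TRUE).
#' @param paper_mode fit the feature engineering globally instead of within
#'   folds (default FALSE).
#' @param grid_search tune hyperparameters by inner 3-fold search over
#'   [default_grid()] before fitting each fold (default FALSE).
#' @return object of class `emg_benchmark`: named list of per-model reports
#'   (class `emg_metrics_report`), each with `model`, `per_class` (percent
#'   metrics, one row per class), `overall` (macro means and overall
#'   accuracy, percent), `confusion` (pooled), `auc_folds`, `error`.
#' @export
run_benchmark <- function(features, labels = NULL,
                          models = default_model_specs(), k = 5L, seed = 1L,
                          retention = 0.999, engineer = TRUE,
                          paper_mode = FALSE, grid_search = FALSE) {
  if (inherits(features, "emg_feature_matrix")) {
    labels <- labels %||% features$labels
    x <- features$values
  } else x <- as.matrix(features)
  if (is.null(labels) || length(labels) != nrow(x))
    stop_data("labels must align with feature rows")
  labels <- as.integer(labels)
  n_class <- max(labels)
  folds <- stratified_kfold(labels, k, seed)

  if (engineer && paper_mode) {
    zs <- zscore_fit(x)
    fit <- pca_fit_transform(zscore_transform(x, zs), retention)
    x_global <- fit$projected
  }

  reports <- lapply(models, function(spec) {
    res <- tryCatch({
      cm <- matrix(0, n_class, n_class)
      auc_folds <- matrix(NA_real_, nrow = k, ncol = n_class)
      for (f in seq_len(k)) {
        tr <- folds[[f]]$train
        te <- folds[[f]]$test
        if (engineer && !paper_mode) {
          eng <- engineer_fold(x[tr, , drop = FALSE], x[te, , drop = FALSE],
                               retention)
          xtr <- eng$train; xte <- eng$test
        } else if (engineer) {
          xtr <- x_global[tr, , drop = FALSE]
          xte <- x_global[te, , drop = FALSE]
        } else {
          xtr <- x[tr, , drop = FALSE]
          xte <- x[te, , drop = FALSE]
        }
        fit_seed <- seed * 131L + f
        use_spec <- if (grid_search)
          grid_search_spec(spec, xtr, labels[tr], fit_seed, n_class)
        else spec
        model <- fit_classifier(use_spec, xtr, labels[tr], seed = fit_seed,
                                n_class = n_class)
        pred <- predict_classifier(model, xte)
        cm <- cm + confusion_matrix(labels[te], pred$class, n_class)
        for (cl in seq_len(n_class)) {
          auc_folds[f, cl] <- tryCatch(
            roc_auc_ovr(pred$scores, labels[te], cl),
            emgpipe_auc_error = function(e) {
              warning(conditionMessage(e))
              NA_real_
            })
        }
      }
      per_class <- t(vapply(seq_len(n_class), function(cl)
        precision_recall_f1_acc(cm, cl), numeric(4)))
      auc <- colMeans(auc_folds, na.rm = TRUE)
      per_class <- data.frame(class = seq_len(n_class), 100 * per_class,
                              auc = 100 * auc)
      overall <- list(precision = mean(per_class$precision),
                      recall = mean(per_class$recall),
                      f1 = mean(per_class$f1),
                      accuracy = 100 * overall_accuracy(cm),
                      auc = mean(per_class$auc))
      structure(list(model = spec$name, per_class = per_class,
                     overall = overall, confusion = cm,
                     auc_folds = auc_folds, error = NULL),
                class = "emg_metrics_report")
    }, error = function(e) {
      structure(list(model = spec$name, per_class = NULL, overall = NULL,
                     confusion = NULL, auc_folds = NULL,
                     error = conditionMessage(e)),
                class = "emg_metrics_report")
    })
    res
  })
  names(reports) <- vapply(models, `[[`, character(1), "name")
  structure(reports, class = "emg_benchmark")
}

#' @export
print.emg_metrics_report <- function(x, ...) {
  if (!is.null(x$error)) {
    cat(sprintf("<emg_metrics_report> %s: FAILED (%s)\n", x$model, x$error))
    return(invisible(x))
  }
  cat(sprintf("<emg_metrics_report> %s\n", x$model))
  print(round(x$per_class, 2), row.names = FALSE)
  ov <- x$overall
  cat(sprintf(
    "overall: precision %.2f recall %.2f F1 %.2f accuracy %.2f AUC %.2f\n",
    ov$precision, ov$recall, ov$f1, ov$accuracy, ov$auc))
  invisible(x)
}

#' @export
print.emg_benchmark <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

metric_rows <- c(precision = "Precision", recall = "Recall",
                 f1 = "F1-score", accuracy = "Accuracy", auc = "AUC")

report_table <- function(report) {
  pc <- report$per_class
  m <- t(as.matrix(pc[, names(metric_rows)]))
  dimnames(m) <- list(unname(metric_rows), paste("Class", pc$class))
  round(m, 2)
}

#' Write benchmark tables
#'
#' Emits one per-class table per model (5 metrics x classes, percent with
#' two decimals, round-half-even) plus an overall summary table
#' (metrics x models), each as CSV and as aligned text.
#'
#' @param reports an `emg_benchmark` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
emit_tables <- function(reports, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  slug <- function(s) gsub("[^a-z0-9]+", "_", tolower(s))
  for (r in reports) {
    if (!is.null(r$error)) next
    m <- report_table(r)
    base <- file.path(dir, paste0("table_", slug(r$model)))
    df <- data.frame(Metric = rownames(m), m, check.names = FALSE)
    data.table::fwrite(df, paste0(base, ".csv"))
    writeLines(capture_table(m, r$model), paste0(base, ".txt"))
    paths <- c(paths, paste0(base, ".csv"), paste0(base, ".txt"))
  }
  ok <- Filter(function(r) is.null(r$error), reports)
  if (length(ok) > 0) {
    ov <- vapply(ok, function(r) unlist(r$overall[names(metric_rows)]),
                 numeric(length(metric_rows)))
    ov <- round(matrix(ov, nrow = length(metric_rows),
                       dimnames = list(unname(metric_rows),
                                       vapply(ok, `[[`, character(1), "model"))),
                2)
    base <- file.path(dir, "table_overall")
    data.table::fwrite(data.frame(Metric = rownames(ov), ov,
                                  check.names = FALSE),
                       paste0(base, ".csv"))
    writeLines(capture_table(ov, "Overall"), paste0(base, ".txt"))
    paths <- c(paths, paste0(base, ".csv"), paste0(base, ".txt"))
  }
  invisible(paths)
}

capture_table <- function(m, title) {
  c(title, utils::capture.output(print(format(m, nsmall = 2), quote = FALSE)))
}
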