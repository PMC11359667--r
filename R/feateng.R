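#' Fit and apply per-column z-score standardization
#'
#' `zscore_fit()` learns per-column means and sample SDs (denominator
#' `N - 1`) on training rows; `zscore_transform()` applies stored parameters
#' to any matrix with the same columns, so held-out rows are standardized
#' with training statistics only (no test-set leakage).
#'
#' @param x numeric matrix (rows = segments).
#' @param fit parameters returned by `zscore_fit()`.
#' @return `zscore_fit()`: list with `center`, `scale`;
#'   `zscore_transform()`: standardized matrix.
#' @export
zscore_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  bad <- which(scale == 0 | !is.finite(scale))
  if (length(bad) > 0)
    stop_data(sprintf("constant column cannot be z-scored: %s",
                      paste(colnames(x)[bad] %||% bad, collapse = ", ")))
  list(center = center, scale = scale)
}

#' @rdname zscore_fit
#' @export
zscore_transform <- function(x, fit) {
  sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
}

#' Audit highly correlated feature pairs
#'
#' Reports all unordered column pairs whose absolute Pearson correlation
#' reaches the threshold, sorted by `|r|` descending. The audit is
#' diagnostic only: no columns are dropped, since downstream redundancy is
#' resolved by PCA rather than deletion.
#'
#' @param x numeric matrix with at least two rows.
#' @param threshold absolute correlation threshold in `[0, 1]` (default 0.90).
#' @return data.frame with columns `col_i`, `col_j` (column names or
#'   indices) and `r`.
#' @export
correlation_audit <- function(x, threshold = 0.90) {
  if (nrow(x) < 2) stop_data("correlation audit needs at least two rows")
  r <- cor(x)
  r[lower.tri(r, diag = TRUE)] <- NA
  hit <- which(abs(r) >= threshold - 1e-12, arr.ind = TRUE)
  nm <- colnames(x) %||% as.character(seq_len(ncol(x)))
  out <- data.frame(col_i = nm[hit[, 1]], col_j = nm[hit[, 2]],
                    r = r[hit], stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Fit PCA retaining a cumulative explained-variance target
#'
#' Principal components are the eigenvectors of the sample covariance of the
#' (standardized) input, ordered by eigenvalue. The number of retained
#' components `k` is the smallest count whose cumulative explained-variance
#' ratio reaches `retention`. The fitted center and basis are stored so
#' held-out rows can be projected with training parameters only.
#'
#' @param x numeric matrix, typically already z-scored.
#' @param retention cumulative explained-variance target in `(0, 1]`
#'   (default 0.999).
#' @param labels optional integer class ids (1..7) carried into the result
#'   together with their one-hot encoding.
#' @param fit an `emg_pca` object returned by `pca_fit_transform()`.
#' @return `pca_fit_transform()`: object of class `emg_pca` with `projected`
#'   (rows x k), `center`, `rotation` (all components), `explained_ratio`,
#'   `k`, `cumulative_variance`, and optionally `labels` / `onehot`.
#'   `pca_transform()`: a rows x k matrix for new data.
#' @export
pca_fit_transform <- function(x, retention = 0.999, labels = NULL) {
  if (!is.numeric(retention) || length(retention) != 1 ||
      retention <= 0 || retention > 1)
    stop_config("retention must lie in (0, 1]")
  if (nrow(x) < 2) stop_data("PCA needs at least two rows")
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  cumvar <- cumsum(evr)
  k <- which(cumvar >= retention - 1e-9)[1]
  if (is.na(k)) k <- length(evr)
  structure(list(
    projected = pr$x[, seq_len(k), drop = FALSE],
    center = pr$center,
    rotation = pr$rotation,
    explained_ratio = evr,
    k = as.integer(k),
    cumulative_variance = cumvar[k],
    labels = labels,
    onehot = if (!is.null(labels)) onehot(labels) else NULL),
    class = "emg_pca")
}

#' @rdname pca_fit_transform
#' @export
pca_transform <- function(x, fit) {
  stopifnot(inherits(fit, "emg_pca"))
  sweep(x, 2, fit$center) %*% fit$rotation[, seq_len(fit$k), drop = FALSE]
}

#' @export
print.emg_pca <- function(x, ...) {
  cat(sprintf(
    "<emg_pca> %d rows, k = %d components, cumulative variance %.5f\n",
    nrow(x$projected), x$k, x$cumulative_variance))
  invisible(x)
}

#' One-hot encode class labels
#'
#' @param labels integer class ids in `1..n_class`.
#' @param n_class number of classes (default 7).
#' @return `length(labels)` x `n_class` 0/1 matrix; each row sums to 1 and
#'   `max.col()` inverts the encoding.
#' @export
onehot <- function(labels, n_class = 7L) {
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > n_class))
    stop_data(sprintf("labels must lie in 1..%d", n_class))
  m <- matrix(0L, nrow = length(labels), ncol = n_class,
              dimnames = list(NULL, paste0("class", seq_len(n_class))))
  m[cbind(seq_along(labels), labels)] <- 1L
  m
}

#' Standardize and project a feature matrix
#'
#' Convenience wrapper chaining [zscore_fit()] / [zscore_transform()] and
#' [pca_fit_transform()] on a feature matrix, keeping both fitted transforms
#' for out-of-sample use.
#'
#' @param fm an `emg_feature_matrix`.
#' @param retention cumulative explained-variance target (default 0.999).
#' @return list with `pca` (`emg_pca`, including `projected`, `labels`,
#'   `onehot`) and `zscore` (standardization parameters).
#' @export
engineer_features <- function(fm, retention = 0.999) {
  stopifnot(inherits(fm, "emg_feature_matrix"))
  zs <- zscore_fit(fm$values)
  std <- zscore_transform(fm$values, zs)
  list(pca = pca_fit_transform(std, retention, labels = fm$labels),
       zscore = zs)
}
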