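test_that("z-score standardization fits on training rows only", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  fit <- zscore_fit(x)
  std <- zscore_transform(x, fit)
  expect_equal(std[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_true(all(abs(colMeans(std)) < 1e-10))
  expect_equal(apply(std, 2, sd), c(a = 1, b = 1))
  # out-of-sample value equal to the training mean maps to 0
  out <- zscore_transform(cbind(a = 2, b = 20), fit)
  expect_equal(as.numeric(out), c(0, 0))

  xc <- cbind(a = 1:5, const = rep(3, 5))
  err <- expect_error(zscore_fit(xc), class = "emgpipe_data_error")
  expect_match(conditionMessage(err), "const")
})

test_that("correlation audit reports high-|r| pairs without dropping columns", {
  set.seed(10)
  base <- rnorm(200)
  x <- cbind(u = base, v = base, w = rnorm(200), z = -base + rnorm(200, sd = 1e-3))
  audit <- correlation_audit(x, 0.90)
  expect_true(all(c("u", "v") %in% unlist(audit[1, 1:2])))
  expect_equal(audit$r[1], 1)
  expect_true(all(abs(audit$r) >= 0.90))
  expect_false("w" %in% c(audit$col_i, audit$col_j))

  strict <- correlation_audit(x, 1.0)
  expect_identical(nrow(strict), 1L)  # only the exact duplicate

  # independent columns at n = 10000: no pair reaches 0.90
  set.seed(11)
  big <- matrix(rnorm(10000 * 6), ncol = 6)
  expect_identical(nrow(correlation_audit(big, 0.90)), 0L)
})

test_that("PCA retains the smallest component count reaching the target", {
  set.seed(21)
  # data in an exact 3-dimensional subspace of 80 dimensions
  basis <- qr.Q(qr(matrix(rnorm(80 * 3), ncol = 3)))
  x <- matrix(rnorm(200 * 3), ncol = 3) %*% t(basis)
  fit <- pca_fit_transform(x, retention = 0.999)
  expect_identical(fit$k, 3L)
  expect_equal(fit$cumulative_variance, 1.0)

  # full-rank data at retention 1.0 keeps min(rows - 1, cols) components
  xf <- matrix(rnorm(30 * 8), ncol = 8)
  expect_identical(pca_fit_transform(xf, retention = 1.0)$k, 8L)
  xt <- matrix(rnorm(6 * 10), ncol = 10)
  expect_identical(pca_fit_transform(xt, retention = 1.0)$k, 5L)

  # isotropic Gaussian, 80 dims: half the variance needs about 40 components
  iso <- matrix(rnorm(10000 * 80), ncol = 80)
  kiso <- pca_fit_transform(iso, retention = 0.5)$k
  expect_gte(kiso, 37L)
  expect_lte(kiso, 43L)

  expect_error(pca_fit_transform(xf, retention = 0),
               class = "emgpipe_config_error")
  expect_error(pca_fit_transform(xf, retention = 1.2),
               class = "emgpipe_config_error")
})

test_that("PCA basis is orthonormal, reconstruction exact, cumvar monotone", {
  set.seed(31)
  x <- matrix(rnorm(120 * 20), ncol = 20)
  fit <- pca_fit_transform(x, retention = 1.0)

  g <- crossprod(fit$rotation[, seq_len(fit$k)])
  expect_lt(max(abs(g - diag(fit$k))), 1e-10)

  recon <- fit$projected %*% t(fit$rotation[, seq_len(fit$k)])
  recon <- sweep(recon, 2, fit$center, "+")
  expect_lt(max(abs(recon - x)), 1e-8)

  expect_true(all(diff(fit$explained_ratio) <= 1e-12))
  expect_true(all(diff(cumsum(fit$explained_ratio)) >= -1e-12))
  expect_lte(sum(fit$explained_ratio), 1 + 1e-9)

  # held-out projection uses stored parameters
  xa <- x[1:100, ]; xb <- x[101:120, ]
  fa <- pca_fit_transform(xa, retention = 0.9)
  pb <- pca_transform(xb, fa)
  expect_identical(dim(pb), c(20L, fa$k))
  expect_equal(pca_transform(xa, fa), fa$projected[, seq_len(fa$k)],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("one-hot encoding is exact and invertible", {
  lab <- c(3L, 1L, 7L, 3L)
  oh <- onehot(lab)
  expect_identical(dim(oh), c(4L, 7L))
  expect_true(all(rowSums(oh) == 1))
  expect_identical(max.col(oh), as.integer(lab))
  expect_identical(unname(oh[1, 3]), 1L)
  expect_error(onehot(c(0L, 2L)), class = "emgpipe_data_error")
})

test_that("engineer_features chains standardization and projection", {
  fm <- tiny_features(6L, seed = 13L)
  eng <- engineer_features(fm, retention = 0.999)
  expect_identical(nrow(eng$pca$projected), nrow(fm$values))
  expect_gte(eng$pca$cumulative_variance, 0.999)
  expect_identical(eng$pca$labels, fm$labels)
  expect_true(all(rowSums(eng$pca$onehot) == 1))
  # k is minimal: one fewer component falls below the target
  cv <- cumsum(eng$pca$explained_ratio)
  if (eng$pca$k > 1) expect_lt(cv[eng$pca$k - 1], 0.999)
})
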