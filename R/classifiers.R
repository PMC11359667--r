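#' Specify a benchmark classifier
#'
#' The five benchmarked models and their documented default
#' hyperparameters:
#'
#' * `LR` - L2-regularized multinomial logistic regression, `C = 1`
#'   (fit with glmnet, ridge penalty `lambda = 1 / (n * C)`).
#' * `SVM-1` - support vector machine, linear kernel, `C = 1`
#'   (one-vs-rest C-SVC duals solved as quadratic programs).
#' * `SVM-2` - support vector machine, RBF kernel, `C = 1`, bandwidth
#'   `gamma = 1 / (n_features * var(X))`.
#' * `kNN` - k-nearest neighbors, `k = 5`, Euclidean distance; vote ties
#'   are broken toward the lowest class id.
#' * `RF` - random forest, 100 Gini CART trees, unlimited depth,
#'   `mtry = floor(sqrt(n_features))`, seeded bootstrap.
#'
#' @param name one of `"LR"`, `"SVM-1"`, `"SVM-2"`, `"kNN"`, `"RF"`.
#' @param hyperparams named list overriding the defaults above.
#' @param grid optional named list of hyperparameter vectors for inner-fold
#'   grid search (see [default_grid()]).
#' @return object of class `emg_model_spec`.
#' @export
model_spec <- function(name, hyperparams = list(), grid = NULL) {
  name <- match.arg(name, c("LR", "SVM-1", "SVM-2", "kNN", "RF"))
  defaults <- switch(name,
    "LR" = list(C = 1),
    "SVM-1" = list(C = 1, kernel = "linear"),
    "SVM-2" = list(C = 1, kernel = "rbf", gamma = "scale"),
    "kNN" = list(k = 5L),
    "RF" = list(ntree = 100L, mtry = NULL, min_node = 1L))
  hp <- utils::modifyList(defaults, hyperparams)
  structure(list(name = name, hyperparams = hp, grid = grid),
            class = "emg_model_spec")
}

#' Default model set and hyperparameter grids
#'
#' `default_model_specs()` returns the five benchmark models with default
#' hyperparameters. `default_grid()` returns a small documented search grid
#' per model, used only when the benchmark is run with grid search enabled.
#'
#' @param names which models to include.
#' @param name model name.
#' @return a list of [model_spec()] objects / a named list of value vectors.
#' @export
default_model_specs <- function(names = c("LR", "SVM-1", "SVM-2", "kNN", "RF")) {
  lapply(names, model_spec)
}

#' @rdname default_model_specs
#' @export
default_grid <- function(name) {
  switch(name,
    "LR" = list(C = c(0.1, 1, 10)),
    "SVM-1" = list(C = c(0.1, 1, 10)),
    "SVM-2" = list(C = c(0.1, 1, 10)),
    "kNN" = list(k = c(3L, 5L, 7L)),
    "RF" = list(mtry_factor = c(0.5, 1, 2)),
    stop_config(paste("unknown model name:", name)))
}

kernel_matrix <- function(x1, x2, kernel, gamma = NULL) {
  if (kernel == "linear") return(tcrossprod(x1, x2))
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# one-vs-rest binary C-SVC dual:
#   max sum(alpha) - 1/2 t(alpha) Q alpha,  Q = (y y') * K,
#   s.t. 0 <= alpha <= C, sum(alpha * y) = 0
svm_fit_binary <- function(K, ybin, C) {
  n <- length(ybin)
  D <- (ybin %o% ybin) * K
  amat <- cbind(ybin, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  ridge <- 1e-8 * (mean(diag(D)) + 1)
  sol <- NULL
  for (i in 1:6) {
    sol <- tryCatch(
      quadprog::solve.QP(D + diag(ridge, n), rep(1, n), amat, bvec, meq = 1),
      error = function(e) NULL)
    if (!is.null(sol)) break
    ridge <- ridge * 100
  }
  if (is.null(sol)) stop_data("SVM dual quadratic program failed to solve")
  alpha <- pmin(pmax(sol$solution, 0), C)
  coef <- alpha * ybin
  eps <- 1e-6 * C
  margin <- alpha > eps & alpha < C - eps
  use <- if (any(margin)) margin else alpha > eps
  b <- if (any(use)) mean(ybin[use] - as.vector(K[use, , drop = FALSE] %*% coef))
       else 0
  list(coef = coef, b = b)
}

#' Fit a benchmark classifier
#'
#' Fits the model described by `spec` to a numeric matrix of engineered (or
#' raw) features and integer class labels. Only the random forest consumes
#' randomness; it is fully reproducible under `seed`.
#'
#' @param spec an [model_spec()] object.
#' @param x numeric matrix, rows = segments.
#' @param y integer class labels in `1..n_class`.
#' @param seed integer seed for models with internal randomness.
#' @param n_class number of classes (default 7).
#' @return object of class `emg_model`.
#' @export
fit_classifier <- function(spec, x, y, seed = 1L, n_class = 7L) {
  stopifnot(inherits(spec, "emg_model_spec"))
  y <- as.integer(y)
  hp <- spec$hyperparams
  fit <- switch(spec$name,
    "LR" = {
      lam <- 1 / (nrow(x) * hp$C)
      glmnet::glmnet(x, factor(y, levels = seq_len(n_class)),
                     family = "multinomial", alpha = 0, lambda = lam,
                     standardize = FALSE)
    },
    "SVM-1" = ,
    "SVM-2" = {
      gamma <- NULL
      if (hp$kernel == "rbf") {
        gamma <- hp$gamma
        if (identical(gamma, "scale"))
          gamma <- 1 / (ncol(x) * stats::var(as.vector(x)))
      }
      K <- kernel_matrix(x, x, hp$kernel, gamma)
      ovr <- lapply(seq_len(n_class), function(cl) {
        ybin <- ifelse(y == cl, 1, -1)
        if (all(ybin == 1) || all(ybin == -1))
          stop_data(sprintf("class %d is absent from the training data", cl))
        svm_fit_binary(K, ybin, hp$C)
      })
      list(x_train = x, kernel = hp$kernel, gamma = gamma, ovr = ovr)
    },
    "kNN" = list(x_train = x, y_train = y, k = as.integer(hp$k)),
    "RF" = {
      mtry <- hp$mtry %||% max(1L, floor(sqrt(ncol(x))))
      forest <- with_seed(seed,
        cpp_rf_grow(x, y - 1L, n_class, as.integer(hp$ntree),
                    as.integer(mtry), as.integer(hp$min_node)))
      list(forest = forest, ntree = as.integer(hp$ntree))
    })
  structure(list(name = spec$name, spec = spec, fit = fit,
                 n_class = as.integer(n_class)),
            class = "emg_model")
}

#' Predict classes and per-class scores
#'
#' @param model an `emg_model` from [fit_classifier()].
#' @param x numeric matrix of rows to classify.
#' @return list with `scores` (rows x n_class numeric matrix: probabilities
#'   for LR, decision values for SVM, vote fractions for kNN/RF) and `class`
#'   (integer labels, argmax of the scores with ties broken toward the
#'   lowest class id).
#' @export
predict_classifier <- function(model, x) {
  stopifnot(inherits(model, "emg_model"))
  K <- model$n_class
  scores <- switch(model$name,
    "LR" = {
      p <- predict(model$fit, newx = x, type = "response")
      matrix(p, nrow = nrow(x), ncol = K)
    },
    "SVM-1" = ,
    "SVM-2" = {
      Kt <- kernel_matrix(x, model$fit$x_train, model$fit$kernel,
                          model$fit$gamma)
      vapply(model$fit$ovr,
             function(m) as.vector(Kt %*% m$coef) + m$b,
             numeric(nrow(x)))
    },
    "kNN" = {
      nn <- FNN::get.knnx(model$fit$x_train, x, k = model$fit$k)$nn.index
      votes <- matrix(0, nrow(x), K)
      for (j in seq_len(ncol(nn))) {
        lab <- model$fit$y_train[nn[, j]]
        votes[cbind(seq_len(nrow(x)), lab)] <-
          votes[cbind(seq_len(nrow(x)), lab)] + 1
      }
      votes / model$fit$k
    },
    "RF" = cpp_rf_votes(model$fit$forest, x, K) / model$fit$ntree)
  if (nrow(x) == 1) scores <- matrix(scores, nrow = 1)
  colnames(scores) <- paste0("class", seq_len(K))
  list(scores = scores, class = max.col(scores, ties.method = "first"))
}
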