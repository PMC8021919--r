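# Conventional ML brain-age baselines: ridge regression (closed form,
# unpenalized intercept, matching the scikit-learn Ridge convention) and
# RBF-kernel epsilon-SVR (libsvm via e1071), under nested 10-fold
# cross-validation with fixed hyperparameter grids and negative-MAE
# selection.

#' Nested cross-validation configuration
#'
#' Defaults reproduce the published protocol: 10 outer and 10 inner folds,
#' lambda grid {0.001, 0.01, 1, 10, 100} for ridge, C and gamma grids
#' {0.001, 0.01, 0.1, 1, 10, 100, 1000} for SVR, model selection by mean
#' negative MAE in the inner loop.
#'
#' @param k_outer,k_inner fold counts (>= 2).
#' @param ridge_lambda_grid ridge penalty grid.
#' @param svr_C_grid,svr_gamma_grid SVR grids.
#' @param svr_epsilon epsilon-insensitive tube width (conventional default
#'   0.1).
#' @param standardize z-score features within each training split (required
#'   for a scale-free gamma grid).
#' @param seed integer seed controlling fold assignment.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(k_outer = 10L, k_inner = 10L,
                      ridge_lambda_grid = c(0.001, 0.01, 1, 10, 100),
                      svr_C_grid = c(0.001, 0.01, 0.1, 1, 10, 100, 1000),
                      svr_gamma_grid = c(0.001, 0.01, 0.1, 1, 10, 100, 1000),
                      svr_epsilon = 0.1, standardize = TRUE, seed = 1L) {
  if (k_outer < 2 || k_inner < 2) stopf("fold counts must be >= 2")
  if (!length(ridge_lambda_grid) || !length(svr_C_grid) ||
      !length(svr_gamma_grid)) stopf("hyperparameter grids must be non-empty")
  structure(list(k_outer = as.integer(k_outer), k_inner = as.integer(k_inner),
                 ridge_lambda_grid = ridge_lambda_grid,
                 svr_C_grid = svr_C_grid, svr_gamma_grid = svr_gamma_grid,
                 svr_epsilon = svr_epsilon, standardize = standardize,
                 seed = as.integer(seed)),
            class = "cv_config")
}

# --- internal fitting primitives -------------------------------------------

.scale_stats <- function(X, standardize) {
  if (standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    sdv[sdv < 1e-12] <- 1
  } else {
    mu <- rep(0, ncol(X)); sdv <- rep(1, ncol(X))
  }
  list(mu = mu, sd = sdv)
}

.scale_apply <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

# Closed-form ridge with unpenalized intercept on (already scaled) X.
.ridge_fit <- function(X, y, lambda) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  A <- crossprod(Xc)
  diag(A) <- diag(A) + lambda
  beta <- solve(A, crossprod(Xc, y - ym))
  list(beta = as.numeric(beta), intercept = ym - sum(xm * beta), xm = xm)
}

.fit_one <- function(X, y, algorithm, hp, config) {
  st <- .scale_stats(X, config$standardize)
  Xs <- .scale_apply(X, st)
  fit <- switch(algorithm,
    ridge = .ridge_fit(Xs, y, hp$lambda),
    svr_rbf = e1071::svm(x = Xs, y = y, type = "eps-regression",
                         kernel = "radial", cost = hp$C, gamma = hp$gamma,
                         epsilon = config$svr_epsilon, scale = FALSE),
    stopf("unknown algorithm '%s'", algorithm))
  list(fit = fit, st = st, algorithm = algorithm, hp = hp)
}

.predict_one <- function(model, X) {
  Xs <- .scale_apply(X, model$st)
  if (model$algorithm == "ridge")
    as.numeric(Xs %*% model$fit$beta + model$fit$intercept)
  else
    as.numeric(predict(model$fit, Xs))
}

.hp_grid <- function(algorithm, config) {
  if (algorithm == "ridge")
    data.frame(lambda = config$ridge_lambda_grid)
  else
    expand.grid(C = config$svr_C_grid, gamma = config$svr_gamma_grid,
                KEEP.OUT.ATTRS = FALSE)
}

.fold_ids <- function(n, k, seed) {
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

# Inner-loop grid search: mean negative MAE over inner folds; ties go to
# the first grid row.
.grid_search <- function(X, y, algorithm, config, seed) {
  grid <- .hp_grid(algorithm, config)
  folds <- .fold_ids(nrow(X), config$k_inner, seed)
  score <- vapply(seq_len(nrow(grid)), function(g) {
    hp <- as.list(grid[g, , drop = FALSE])
    maes <- vapply(seq_len(config$k_inner), function(f) {
      tr <- folds != f; te <- !tr
      if (!any(te) || !any(tr)) return(NA_real_)
      m <- .fit_one(X[tr, , drop = FALSE], y[tr], algorithm, hp, config)
      mean(abs(.predict_one(m, X[te, , drop = FALSE]) - y[te]))
    }, numeric(1))
    -mean(maes, na.rm = TRUE)
  }, numeric(1))
  as.list(grid[which.max(score), , drop = FALSE])
}

#' Nested cross-validation for a brain-age baseline
#'
#' For each outer fold, an inner k-fold grid search (scored by mean negative
#' MAE) selects the hyperparameters, the model is refit on the outer
#' training split, and the outer test split is predicted; every subject is
#' predicted exactly once and pooled out-of-fold metrics are reported.
#' Feature standardization statistics are computed within each training
#' split only.
#'
#' @param features numeric matrix (subjects x features) or `feature_table`.
#' @param ages numeric vector of chronological ages.
#' @param algorithm `"ridge"` or `"svr_rbf"`.
#' @param config a [cv_config()].
#' @return object of class `nested_cv`: out-of-fold `predictions`, `folds`,
#'   per-fold `chosen` hyperparameters, pooled `mae`, `rmse`, `r2`.
#' @export
nested_cv <- function(features, ages, algorithm = c("ridge", "svr_rbf"),
                      config = cv_config()) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(features)
  assert_finite(X, "features")
  n <- nrow(X)
  if (n < 2 * config$k_outer)
    stopf("need at least %d subjects for %d outer folds",
          2 * config$k_outer, config$k_outer)
  folds <- .fold_ids(n, config$k_outer, hash_seed(config$seed, "outer"))
  pred <- rep(NA_real_, n)
  chosen <- vector("list", config$k_outer)
  for (f in seq_len(config$k_outer)) {
    tr <- folds != f
    if (var(ages[tr]) < 1e-12) stopf("constant ages in outer-train fold %d", f)
    hp <- .grid_search(X[tr, , drop = FALSE], ages[tr], algorithm, config,
                       hash_seed(config$seed, "inner", f))
    m <- .fit_one(X[tr, , drop = FALSE], ages[tr], algorithm, hp, config)
    pred[!tr] <- .predict_one(m, X[!tr, , drop = FALSE])
    chosen[[f]] <- hp
  }
  if (var(ages) < 1e-12) stopf("R^2 undefined: constant ages")
  res <- structure(list(
    algorithm = algorithm, predictions = pred, ages = ages, folds = folds,
    chosen = chosen,
    mae = mean(abs(pred - ages)),
    rmse = sqrt(mean((pred - ages)^2)),
    r2 = 1 - sum((pred - ages)^2) / sum((ages - mean(ages))^2),
    config = config), class = "nested_cv")
  res
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("nested %d-fold CV, %s: MAE %.3f y, RMSE %.3f y, R2 %.3f (n = %d)\n",
              x$config$k_outer, x$algorithm, x$mae, x$rmse, x$r2,
              length(x$ages)))
  invisible(x)
}

#' Fit the final brain-age estimator on the whole training sample
#'
#' Selects hyperparameters by inner cross-validation on all training rows,
#' then refits on everything. The estimator stores the feature-name schema;
#' prediction aligns columns by name and refuses tables with missing
#' columns.
#'
#' @inheritParams nested_cv
#' @return object of class `brainage_model`.
#' @export
fit_final <- function(features, ages, algorithm = c("ridge", "svr_rbf"),
                      config = cv_config()) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(features)
  assert_finite(X, "features")
  hp <- .grid_search(X, ages, algorithm, config,
                     hash_seed(config$seed, "final"))
  m <- .fit_one(X, ages, algorithm, hp, config)
  structure(list(model = m, schema = colnames(X), hp = hp,
                 algorithm = algorithm, n_train = nrow(X)),
            class = "brainage_model")
}

#' Predict brain age from a fitted estimator
#'
#' @param object a [fit_final()] result.
#' @param newdata feature matrix with named columns matching the training
#'   schema (any column order).
#' @param ... unused.
#' @return numeric vector of predicted ages.
#' @export
predict.brainage_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$schema)) {
    if (is.null(colnames(X)))
      stopf("newdata has no column names; expected schema of %d features",
            length(object$schema))
    missing <- setdiff(object$schema, colnames(X))
    if (length(missing))
      stopf("newdata is missing feature column(s): %s",
            paste(missing, collapse = ", "))
    X <- X[, object$schema, drop = FALSE]
  }
  .predict_one(object$model, X)
}

#' @export
print.brainage_model <- function(x, ...) {
  hp <- paste(names(x$hp), unlist(x$hp), sep = "=", collapse = ", ")
  cat(sprintf("brain-age estimator (%s, %s), trained on %d subjects, %d features\n",
              x$algorithm, hp, x$n_train, length(x$schema)))
  invisible(x)
}

#' @export
coef.brainage_model <- function(object, ...) {
  if (object$algorithm != "ridge") return(NULL)
  c(intercept = object$model$fit$intercept,
    stats::setNames(object$model$fit$beta, object$schema))
}
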