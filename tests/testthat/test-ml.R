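make_linear_cohort <- function(n = 300, p = 30, informative = 20,
                               noise_sd = 2, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("f%02d", seq_len(p))
  beta <- c(runif(informative, -2, 2), rep(0, p - informative))
  age <- as.numeric(40 + X %*% beta + rnorm(n, 0, noise_sd))
  list(X = X, age = age)
}

test_that("nested-CV ridge beats the null model on linear synthetic data", {
  d <- make_linear_cohort()
  cfg <- cv_config(seed = 5)
  cv <- nested_cv(d$X, d$age, "ridge", cfg)
  # null oracle: predict the training mean within the same outer folds
  null_pred <- rep(NA_real_, length(d$age))
  for (f in unique(cv$folds))
    null_pred[cv$folds == f] <- mean(d$age[cv$folds != f])
  null_mae <- mean(abs(null_pred - d$age))
  expect_lt(cv$mae, 0.5 * null_mae)
  expect_true(all(!is.na(cv$predictions)))
  expect_identical(length(cv$chosen), 10L)
})

test_that("pure-noise features give near-zero out-of-fold R^2", {
  set.seed(6)
  X <- matrix(rnorm(200 * 15), 200, 15)
  age <- runif(200, 20, 80)
  cv <- nested_cv(X, age, "ridge", cv_config(seed = 7))
  expect_lte(cv$r2, 0.05)
})

test_that("nested CV is deterministic given its seed", {
  d <- make_linear_cohort(n = 60, p = 5, informative = 3)
  a <- nested_cv(d$X, d$age, "ridge", cv_config(seed = 9))
  b <- nested_cv(d$X, d$age, "ridge", cv_config(seed = 9))
  expect_identical(a$folds, b$folds)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$chosen, b$chosen)
})

test_that("SVR-RBF nested CV runs the full grid and predicts sensibly", {
  d <- make_linear_cohort(n = 60, p = 4, informative = 4, noise_sd = 1)
  cv <- nested_cv(d$X, d$age, "svr_rbf", cv_config(seed = 3))
  expect_true(all(c("C", "gamma") %in% names(cv$chosen[[1]])))
  expect_lt(cv$mae, mean(abs(d$age - mean(d$age))))
})

test_that("small ridge penalty approaches OLS on a noise-free problem", {
  set.seed(8)
  X <- matrix(rnorm(100 * 5), 100, 5)
  y <- as.numeric(10 + X %*% c(1, -2, 3, 0.5, -1))
  m <- brainagekit:::.fit_one(X, y, "ridge", list(lambda = 0.001),
                              cv_config(standardize = FALSE))
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(m$fit$beta - ols[-1])), 1e-3)
})

test_that("the final estimator recovers a noise-free affine model", {
  set.seed(12)
  X <- matrix(rnorm(120 * 6), 120, 6)
  colnames(X) <- sprintf("f%d", 1:6)
  age <- as.numeric(35 + X %*% c(2, -1, 0.5, 1, -2, 0.3))
  fit <- fit_final(X[1:100, ], age[1:100], "ridge",
                   cv_config(k_inner = 5, seed = 2))
  pred <- predict(fit, X[101:120, ])
  expect_lt(mean(abs(pred - age[101:120])), 0.1)
})

test_that("prediction aligns feature columns by name and flags gaps", {
  set.seed(13)
  X <- matrix(rnorm(80 * 4), 80, 4)
  colnames(X) <- c("a", "b", "c", "d")
  age <- as.numeric(30 + X %*% c(1, 2, 3, 4))
  fit <- fit_final(X, age, "ridge", cv_config(k_inner = 5, seed = 1))
  perm <- X[, c("d", "b", "a", "c")]
  expect_equal(predict(fit, perm), predict(fit, X))
  expect_error(predict(fit, X[, 1:3]), "missing feature column")
  # per-row predictions do not depend on the rest of the table
  one <- predict(fit, X[5, , drop = FALSE])
  expect_equal(one, predict(fit, X)[5])
})

test_that("constant-age folds are rejected", {
  X <- matrix(rnorm(40 * 3), 40, 3)
  expect_error(nested_cv(X, rep(50, 40), "ridge", cv_config(seed = 1)),
               "constant ages")
})
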