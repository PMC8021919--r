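test_that("brain-age delta is predicted minus chronological age", {
  expect_equal(brain_age_delta(prediction_batch(30, 33.5)), 3.5)
  y <- runif(10, 20, 80)
  expect_equal(brain_age_delta(prediction_batch(y, y)), rep(0, 10))
  # unbiased predictor: mean delta within 3 SE of zero
  set.seed(14)
  y <- runif(500, 20, 80)
  yp <- y + rnorm(500, 0, 3)
  d <- brain_age_delta(prediction_batch(y, yp))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(500))
})

test_that("KL divergence matches the closed-form toy computation", {
  kld <- kl_divergence(c(0.5, 0.5), c(0.9, 0.1))
  expect_equal(kld, 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-12)
  expect_equal(round(kld, 4), 0.5108)
  expect_identical(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  # asymmetry
  expect_false(isTRUE(all.equal(kl_divergence(c(0.5, 0.5), c(0.9, 0.1)),
                                kl_divergence(c(0.9, 0.1), c(0.5, 0.5)))))
  expect_gte(kl_divergence(c(0.2, 0.8), c(0.6, 0.4)), 0)
  expect_error(kl_divergence(c(1, 0), c(0, 1)), "zero mass")
})

test_that("metric report reproduces hand metrics and perfect prediction", {
  b <- prediction_batch(c(10, 20, 30), c(12, 18, 33))
  r <- metric_report(b)
  expect_equal(r$mae, 7 / 3)
  expect_equal(r$rmse, sqrt((4 + 4 + 9) / 3))
  expect_lte(r$mae, r$rmse)
  y <- runif(50, 20, 80)
  perfect <- metric_report(prediction_batch(y, y))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$kld, 0, tolerance = 1e-9)
})

test_that("metric report flags undefined r2/rho on constant ages", {
  b <- prediction_batch(rep(40, 5), c(39, 41, 40, 40, 42))
  expect_warning(r <- metric_report(b), "undefined")
  expect_true(is.na(r$r2) && is.na(r$rho))
  expect_false(is.na(r$mae))
})

test_that("mae <= rmse over random batches", {
  set.seed(15)
  for (i in 1:20) {
    y <- runif(30, 17, 90)
    r <- metric_report(prediction_batch(y, y + rnorm(30, 0, 5)))
    expect_lte(r$mae, r$rmse + 1e-12)
  }
})

test_that("bias fitting recovers an exact linear bias", {
  y <- seq(20, 80, length.out = 40)
  yp <- y + (5 - 0.2 * y)
  bm <- fit_bias(prediction_batch(y, yp))
  expect_equal(bm$intercept, 5, tolerance = 1e-10)
  expect_equal(bm$slope, -0.2, tolerance = 1e-10)
  expect_error(fit_bias(prediction_batch(rep(50, 5), rnorm(5, 50))),
               "constant ages")
  # age-independent delta: slope within 3 SE of zero
  set.seed(16)
  y2 <- runif(400, 20, 80)
  yp2 <- y2 + rnorm(400, 2, 3)
  bm2 <- fit_bias(prediction_batch(y2, yp2))
  se <- summary(lm(I(yp2 - y2) ~ y2))$coefficients[2, 2]
  expect_lt(abs(bm2$slope), 3 * se)
})

test_that("bias correction residualizes delta against age", {
  null_bm <- structure(list(intercept = 0, slope = 0), class = "bias_model")
  y <- runif(30, 20, 80); yp <- y + rnorm(30)
  b <- prediction_batch(y, yp)
  expect_equal(apply_bias(null_bm, b)$y_pred, b$y_pred)
  # regression-to-the-mean predictor, fit and applied on the same data:
  # corrected delta exactly orthogonal to age
  set.seed(17)
  y <- runif(200, 17, 90)
  yp <- 0.5 * y + 20 + rnorm(200, 0, 2)
  b <- prediction_batch(y, yp)
  bm <- fit_bias(b)
  corrected <- apply_bias(bm, b)
  expect_lt(abs(cor(brain_age_delta(corrected), y)), 1e-8)
})

test_that("bias correction generalizes to held-out data with the same bias", {
  set.seed(18)
  y_tr <- runif(300, 17, 90); y_te <- runif(300, 17, 90)
  mk <- function(y) prediction_batch(y, 0.5 * y + 20 + rnorm(length(y), 0, 2))
  train <- mk(y_tr); test <- mk(y_te)
  rho_before <- abs(cor(brain_age_delta(test), y_te, method = "spearman"))
  expect_gt(rho_before, 0.3)
  corrected <- apply_bias(fit_bias(train), test)
  rho_after <- abs(cor(brain_age_delta(corrected), y_te,
                       method = "spearman"))
  expect_lt(rho_after, 0.1)
})

test_that("bias correction perturbs MAE by at most the fitted line's range", {
  set.seed(19)
  y <- runif(100, 17, 90)
  b <- prediction_batch(y, y + rnorm(100, 1, 4))
  bm <- fit_bias(b)
  corrected <- apply_bias(bm, b)
  bound <- max(abs(bm$intercept + bm$slope * y))
  expect_lte(abs(metric_report(corrected)$mae - metric_report(b)$mae),
             bound + 1e-12)
})
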