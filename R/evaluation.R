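# Evaluation of brain-age predictions: error metrics, the KL divergence
# between the chronological and predicted age distributions, and the
# chronological-age bias correction (delta residualized on age, after
# Cole's method).

#' Brain-age delta
#'
#' Predicted brain age minus chronological age, per subject.
#'
#' @param batch a [prediction_batch()].
#' @return numeric vector.
#' @export
brain_age_delta <- function(batch) batch$y_pred - batch$y

#' Kullback-Leibler divergence between two discrete distributions
#'
#' `sum(p * log(p / q))` in nats, with optional additive smoothing `eps`
#' applied to both count/probability vectors before renormalization.
#' Zero-probability bins of `p` contribute 0 when `eps = 0`.
#'
#' @param p,q non-negative vectors of equal length (renormalized to sum 1).
#' @param eps additive smoothing (default 0).
#' @return non-negative scalar, nats.
#' @export
kl_divergence <- function(p, q, eps = 0) {
  if (length(p) != length(q)) stopf("p and q lengths differ")
  if (any(p < 0) || any(q < 0)) stopf("negative mass")
  p <- p + eps; q <- q + eps
  p <- p / sum(p); q <- q / sum(q)
  if (any(q == 0 & p > 0)) stopf("q has zero mass where p > 0; use eps > 0")
  sum(ifelse(p > 0, p * log(p / q), 0))
}

# Histogram counts on fixed bins; out-of-range values are clamped into the
# edge bins so no mass is dropped.
.age_hist <- function(x, breaks) {
  x <- pmin(pmax(x, breaks[1]), breaks[length(breaks)])
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = length(breaks) - 1)
}

#' Full metric report for a prediction batch
#'
#' MAE, RMSE and R-squared of predicted vs chronological age; Spearman
#' correlation of the brain-age delta with chronological age; and the KL
#' divergence KLD(P||Q) between the chronological (P) and predicted (Q)
#' age histograms on shared 5-year bins spanning 15-95 years with additive
#' smoothing.
#'
#' @param batch a [prediction_batch()] with at least 3 subjects.
#' @param breaks histogram bin edges, years.
#' @param eps additive smoothing for the KLD histograms.
#' @return object of class `metric_report`: `mae`, `rmse`, `r2`, `rho`,
#'   `kld`, `n`. With constant chronological ages, `r2` and `rho` are `NA`
#'   (undefined).
#' @export
metric_report <- function(batch, breaks = seq(15, 95, by = 5), eps = 1e-6) {
  if (batch$n < 3) stopf("need at least 3 subjects")
  e <- batch$y_pred - batch$y
  constant <- var(batch$y) < 1e-12
  if (constant) warning("constant chronological ages: r2 and rho undefined")
  r2 <- if (constant) NA_real_ else
    1 - sum(e^2) / sum((batch$y - mean(batch$y))^2)
  rho <- if (constant) NA_real_ else
    suppressWarnings(cor(e, batch$y, method = "spearman"))
  kld <- kl_divergence(.age_hist(batch$y, breaks),
                       .age_hist(batch$y_pred, breaks), eps = eps)
  structure(list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)), r2 = r2,
                 rho = rho, kld = kld, n = batch$n),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("n = %d: MAE %.3f y, RMSE %.3f y, R2 %s, Spearman(delta, age) %s, KLD %.4f nats\n",
              x$n, x$mae, x$rmse,
              ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2)),
              ifelse(is.na(x$rho), "NA", sprintf("%.3f", x$rho)), x$kld))
  invisible(x)
}

#' Fit the chronological-age bias model
#'
#' Regression estimators over-predict young and under-predict old subjects
#' (regression toward the mean). The bias model is the OLS fit
#' `delta = a + b * age` on a *training* prediction batch; the fitted line
#' is later subtracted from held-out deltas.
#'
#' @param train_batch a [prediction_batch()] with nonconstant ages.
#' @return object of class `bias_model` with `intercept` and `slope`.
#' @export
fit_bias <- function(train_batch) {
  if (var(train_batch$y) < 1e-12)
    stopf("cannot fit bias model on constant ages")
  fit <- lm(delta ~ age, data = data.frame(
    delta = brain_age_delta(train_batch), age = train_batch$y))
  cf <- coef(fit)
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2])),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("bias model: delta = %.4f %+.4f * age\n", x$intercept, x$slope))
  invisible(x)
}

#' @export
coef.bias_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Apply a fitted bias correction to a prediction batch
#'
#' `corrected_delta = delta - (a + b * age)`; the corrected predicted age
#' is `age + corrected_delta`.
#'
#' @param model a [fit_bias()] result.
#' @param batch a [prediction_batch()].
#' @return a corrected `prediction_batch`.
#' @export
apply_bias <- function(model, batch) {
  corrected <- brain_age_delta(batch) -
    (model$intercept + model$slope * batch$y)
  prediction_batch(batch$y, batch$y + corrected)
}
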