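# Mini-batch training losses for the 3D residual age regressor.
#
# Two bespoke regularizers discourage age-correlated prediction error
# within a mini-batch of N subjects with chronological ages Y and predicted
# ages Y':
#
#   covariance loss  L_cov  = (1/N) * sum_{i,j} ((Y'_i - Y_i) * Y_j)^2
#                           = (1/N) * ||(Y' - Y) %o% Y||_F^2
#   ranking loss     L_rank = (1/N) * sum_{i,j} (Y'_i Y'_j - Y_i Y_j)^2
#                           = (1/N) * ||Y' %o% Y' - Y %o% Y||_F^2
#
# i.e. 1/N times the sum of squared entries of the error-by-age outer
# product, respectively of the difference between the predicted and true
# Gram (outer-product) matrices. Both are non-negative, zero at perfect
# prediction, and differentiable in Y'.

#' Construct a prediction batch
#'
#' Pairs chronological ages `y` with predicted ages `y_pred` for one
#' mini-batch or evaluation set.
#'
#' @param y numeric vector of chronological ages (years).
#' @param y_pred numeric vector of predicted ages, same length.
#' @return object of class `prediction_batch` with fields `y`, `y_pred`,
#'   `n`.
#' @export
prediction_batch <- function(y, y_pred) {
  if (length(y) != length(y_pred)) stopf("y and y_pred lengths differ")
  if (length(y) < 1) stopf("empty batch")
  assert_finite(y, "y"); assert_finite(y_pred, "y_pred")
  structure(list(y = as.numeric(y), y_pred = as.numeric(y_pred),
                 n = length(y)), class = "prediction_batch")
}

#' @export
print.prediction_batch <- function(x, ...) {
  cat(sprintf("prediction batch: n = %d, MAE = %.3f y\n",
              x$n, mean(abs(x$y_pred - x$y))))
  invisible(x)
}

#' Covariance regularization loss
#'
#' `(1/N) * sum_ij ((Y'_i - Y_i) * Y_j)^2`: the mean (over batch rows) of
#' the squared entries of the outer product of the prediction error with
#' the chronological ages. Penalizes error whose magnitude scales with age,
#' i.e. age-covarying bias.
#'
#' @param batch a [prediction_batch()].
#' @return non-negative scalar.
#' @export
covariance_loss <- function(batch) {
  e <- batch$y_pred - batch$y
  sum(e^2) * sum(batch$y^2) / batch$n
}

# dL_cov / dY'_k = (2/N) * E_k * sum(Y^2)
covariance_loss_grad <- function(batch) {
  (2 / batch$n) * (batch$y_pred - batch$y) * sum(batch$y^2)
}

#' Ranking-relationship regularization loss
#'
#' `(1/N) * sum_ij (Y'_i Y'_j - Y_i Y_j)^2`: the mean (over batch rows) of
#' the squared difference between the predicted-age and true-age Gram
#' matrices, preserving the pairwise (ranking) structure of ages within the
#' batch.
#'
#' @param batch a [prediction_batch()].
#' @return non-negative scalar.
#' @export
ranking_loss <- function(batch) {
  d <- tcrossprod(batch$y_pred) - tcrossprod(batch$y)
  sum(d^2) / batch$n
}

# dL_rank / dY' = (4/N) * (Y' Y'^T - Y Y^T) Y'
ranking_loss_grad <- function(batch) {
  d <- tcrossprod(batch$y_pred) - tcrossprod(batch$y)
  (4 / batch$n) * as.numeric(d %*% batch$y_pred)
}

#' Composite training loss
#'
#' The base task loss is the mean absolute error in years (the standard
#' brain-age reporting metric); `cov_reg` and `rank_reg` add the respective
#' regularizer scaled
#' by `reg_weight`.
#'
#' @param batch a [prediction_batch()].
#' @param mode `"plain"`, `"cov_reg"` or `"rank_reg"`.
#' @param reg_weight regularizer weight (default 1e-6, chosen so both terms
#'   are comparable at initialization for age-scale targets).
#' @return scalar loss.
#' @export
composite_loss <- function(batch, mode = c("plain", "cov_reg", "rank_reg"),
                           reg_weight = 1e-6) {
  mode <- match.arg(mode)
  mae <- mean(abs(batch$y_pred - batch$y))
  switch(mode,
         plain = mae,
         cov_reg = mae + reg_weight * covariance_loss(batch),
         rank_reg = mae + reg_weight * ranking_loss(batch))
}

# Subgradient of the composite loss w.r.t. y_pred (sign convention 0 at 0).
composite_loss_grad <- function(batch, mode = c("plain", "cov_reg", "rank_reg"),
                                reg_weight = 1e-6) {
  mode <- match.arg(mode)
  g <- sign(batch$y_pred - batch$y) / batch$n
  if (mode == "cov_reg") g <- g + reg_weight * covariance_loss_grad(batch)
  if (mode == "rank_reg") g <- g + reg_weight * ranking_loss_grad(batch)
  g
}
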