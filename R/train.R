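# SGD training of the residual age regressor.

#' Training configuration for the residual regressor
#'
#' Defaults follow the published schedule: SGD with learning rate 0.1,
#' momentum 0.9, weight decay 0.0005; the learning rate drops by a factor
#' of 10 after 50% and again after 75% of the epochs; 300 epochs at batch
#' size 8 at full scale (pass smaller `epochs` for desk-scale runs).
#'
#' @param lr initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay added to every gradient.
#' @param epochs total training epochs (>= 1).
#' @param batch_size mini-batch size.
#' @param lr_decay_factor divisor applied at 50% and 75% of training.
#' @param loss_mode `"plain"` (MAE), `"cov_reg"` or `"rank_reg"`.
#' @param reg_weight regularizer weight for the `_reg` modes.
#' @param seed integer seed for shuffling and dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 0.1, momentum = 0.9, weight_decay = 5e-4,
                         epochs = 300L, batch_size = 8L,
                         lr_decay_factor = 10,
                         loss_mode = c("plain", "cov_reg", "rank_reg"),
                         reg_weight = 1e-6, seed = 1L) {
  loss_mode <- match.arg(loss_mode)
  if (epochs < 1) stopf("epochs must be >= 1")
  if (lr <= 0 || batch_size < 1) stopf("positive lr and batch_size required")
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_decay_factor = lr_decay_factor, loss_mode = loss_mode,
                 reg_weight = reg_weight, seed = as.integer(seed)),
            class = "train_config")
}

#' Per-epoch learning-rate schedule
#'
#' Constant at `lr`, divided by `factor` for epochs beyond 50% of the
#' total, and again beyond 75% (e.g. 4 epochs at lr 0.1 give 0.1, 0.1,
#' 0.01, 0.001).
#'
#' @param lr initial learning rate.
#' @param epochs total epochs.
#' @param factor decay divisor.
#' @return numeric vector of length `epochs`.
#' @export
lr_schedule <- function(lr, epochs, factor = 10) {
  e <- seq_len(epochs)
  lr / factor^((e > epochs / 2) + (e > 3 * epochs / 4))
}

# Elementwise update over the nested parameter list:
# v <- momentum * v + grad + wd * param ; param <- param - lr * v
.sgd_step <- function(params, grads, vel, lr, momentum, wd) {
  for (nm in names(grads)) {
    gp <- grads[[nm]]
    if (is.list(gp) && !is.null(names(gp)) &&
        all(vapply(gp, function(z) is.list(z) || is.numeric(z), logical(1))) &&
        any(vapply(gp, is.list, logical(1)))) {
      r <- .sgd_step(params[[nm]], gp, vel[[nm]] %||% list(), lr, momentum, wd)
      params[[nm]] <- r$params; vel[[nm]] <- r$vel
    } else if (is.list(gp)) {   # bn gradients: gamma/beta against bn param list
      for (sub in names(gp)) {
        g <- gp[[sub]] + wd * params[[nm]][[sub]]
        v <- momentum * (vel[[nm]][[sub]] %||% 0) + g
        vel[[nm]][[sub]] <- v
        params[[nm]][[sub]] <- params[[nm]][[sub]] - lr * v
      }
    } else {
      g <- gp + wd * params[[nm]]
      v <- momentum * (vel[[nm]] %||% 0) + g
      vel[[nm]] <- v
      params[[nm]] <- params[[nm]] - lr * v
    }
  }
  list(params = params, vel = vel)
}

#' Train the residual age regressor
#'
#' Mini-batch SGD under [train_config()]; after every epoch the validation
#' set is predicted in evaluation mode and a checkpoint record (epoch,
#' learning rate, training loss, validation MAE, and Spearman correlation
#' of the brain-age delta with age) is appended. The record with the
#' smallest validation MAE is flagged as the best checkpoint.
#'
#' @param model a [resnet_build()] result.
#' @param x_train,y_train training volumes `(x,y,z,channel,subject)` and
#'   ages.
#' @param x_val,y_val validation volumes and ages.
#' @param config a [train_config()].
#' @param sex_train,sex_val 0/1 vectors when the spec uses sex input.
#' @param config_id label stored in the checkpoint records.
#' @param keep_weights `"best"` (default), `"all"` (one snapshot per epoch;
#'   desk-scale models only) or `"none"`.
#' @return object of class `resnet_training`: `records` data.frame, `model`
#'   (final weights), `best_epoch`, `best_model`, `checkpoints` (when
#'   `keep_weights = "all"`).
#' @export
train_resnet <- function(model, x_train, y_train, x_val, y_val,
                         config = train_config(),
                         sex_train = NULL, sex_val = NULL,
                         config_id = "model", keep_weights = "best") {
  n <- dim(x_train)[5]
  if (config$batch_size > n) stopf("batch_size exceeds n_train")
  .check_grid(dim(x_train)[1:3])
  lrs <- lr_schedule(config$lr, config$epochs, config$lr_decay_factor)
  vel <- list()
  records <- vector("list", config$epochs)
  best_mae <- Inf; best_model <- NULL; best_epoch <- NA_integer_
  checkpoints <- if (identical(keep_weights, "all"))
    vector("list", config$epochs) else NULL
  with_seed(hash_seed(config$seed, "train", config_id), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      starts <- seq(1, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        xb <- x_train[, , , , idx, drop = FALSE]
        fw <- .resnet_fwd(model, xb, sex = sex_train[idx], training = TRUE,
                          keep_cache = TRUE)
        model <- fw$model
        if (any(!is.finite(fw$pred)))
          stopf("training diverged (non-finite predictions) at epoch %d",
                epoch)
        batch <- prediction_batch(y_train[idx], fw$pred)
        loss <- composite_loss(batch, config$loss_mode, config$reg_weight)
        if (!is.finite(loss))
          stopf("training diverged (non-finite loss) at epoch %d", epoch)
        epoch_loss <- epoch_loss + loss * length(idx)
        dpred <- composite_loss_grad(batch, config$loss_mode,
                                     config$reg_weight)
        grads <- .resnet_bwd(model, fw$cache, dpred)
        st <- .sgd_step(model$params, grads, vel, lrs[epoch],
                        config$momentum, config$weight_decay)
        model$params <- st$params; vel <- st$vel
      }
      val_pred <- .resnet_fwd(model, x_val, sex = sex_val,
                              training = FALSE)$pred
      val_mae <- mean(abs(val_pred - y_val))
      val_rho <- suppressWarnings(
        cor(val_pred - y_val, y_val, method = "spearman"))
      records[[epoch]] <- data.frame(
        config_id = config_id, epoch = epoch, lr = lrs[epoch],
        train_loss = epoch_loss / n, val_mae = val_mae, val_rho = val_rho,
        stringsAsFactors = FALSE)
      if (is.finite(val_mae) && val_mae < best_mae) {
        best_mae <- val_mae; best_epoch <- epoch
        if (!identical(keep_weights, "none")) best_model <- model
      }
      if (identical(keep_weights, "all")) checkpoints[[epoch]] <- model$params
    }
  })
  records <- do.call(rbind, records)
  records$best <- records$epoch == best_epoch
  structure(list(records = records, model = model, best_epoch = best_epoch,
                 best_model = best_model, checkpoints = checkpoints,
                 config = config, config_id = config_id),
            class = "resnet_training")
}

#' @export
print.resnet_training <- function(x, ...) {
  last <- x$records[nrow(x$records), ]
  cat(sprintf("trained '%s' for %d epochs (%s loss): final val MAE %.3f y; best epoch %d (val MAE %.3f y)\n",
              x$config_id, nrow(x$records), x$config$loss_mode,
              last$val_mae, x$best_epoch,
              min(x$records$val_mae)))
  invisible(x)
}
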