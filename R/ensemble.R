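# Ensembling: per-subject median aggregation over member models, the five
# Objective-1 member recipes, and the Objective-2 checkpoint-selection rule
# (filter by validation MAE and |Spearman bias|, rank, take the top eight).

#' Median-aggregate member predictions
#'
#' @param pred_matrix numeric matrix, models x subjects (no missing
#'   entries). For an even member count the median is the mean of the two
#'   central order statistics.
#' @return numeric vector of per-subject ensemble predictions.
#' @export
median_aggregate <- function(pred_matrix) {
  if (!is.matrix(pred_matrix)) pred_matrix <- rbind(pred_matrix)
  if (nrow(pred_matrix) < 1) stopf("need at least one model row")
  if (anyNA(pred_matrix)) stopf("missing entries in prediction matrix")
  apply(pred_matrix, 2, median)
}

#' The five Objective-1 ensemble member recipes
#'
#' Enumerates the published five-member ensemble: (1) T1 + GMV + WMV;
#' (2) the same channels with the ranking-relationship ("second")
#' regularization; (3) the same channels with additional sex input;
#' (4) T1 + GMD + WMD; (5) T1 + GMD + WMD + the stub FLAIR channel. The
#' phantom cohort has a single pseudo-T1 map standing in for both the raw
#' and template-space T1, and a synthetic stub channel in place of the
#' U-Net-synthesized FLAIR.
#'
#' @param available_channels channel names present in the cohort.
#' @param dropout_rate dropout for every member.
#' @return object of class `ensemble_set`: list of 5 recipes (fields
#'   `name`, `channels`, `loss_mode`, `sex_input`, `dropout_rate`),
#'   aggregation = "median".
#' @export
objective1_members <- function(available_channels = PHANTOM_CHANNELS,
                               dropout_rate = 0.1) {
  recipes <- list(
    list(name = "model1-1", channels = c("t1", "gmv", "wmv"),
         loss_mode = "plain", sex_input = FALSE),
    list(name = "model1-2", channels = c("t1", "gmv", "wmv"),
         loss_mode = "rank_reg", sex_input = FALSE),
    list(name = "model1-3", channels = c("t1", "gmv", "wmv"),
         loss_mode = "plain", sex_input = TRUE),
    list(name = "model1-4", channels = c("t1", "gmd", "wmd"),
         loss_mode = "plain", sex_input = FALSE),
    list(name = "model1-5", channels = c("t1", "gmd", "wmd", "flair_stub"),
         loss_mode = "plain", sex_input = FALSE))
  for (r in recipes) {
    missing <- setdiff(r$channels, available_channels)
    if (length(missing))
      stopf("member %s requires missing channel(s): %s",
            r$name, paste(missing, collapse = ", "))
  }
  recipes <- lapply(recipes, function(r) {
    r$dropout_rate <- dropout_rate
    r
  })
  structure(list(members = recipes, aggregation = "median"),
            class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf("ensemble of %d members (aggregation: %s)\n",
              length(x$members), x$aggregation))
  for (r in x$members)
    cat(sprintf("  %s: %s%s%s\n", r$name, paste(r$channels, collapse = "+"),
                if (r$loss_mode != "plain") paste0(" + ", r$loss_mode) else "",
                if (r$sex_input) " + sex" else ""))
  invisible(x)
}

#' Objective-2 checkpoint selection
#'
#' From a pool of per-epoch checkpoint records (e.g. 6 configurations x 300
#' epochs = 1800 checkpoints), keeps those with validation MAE below
#' `mae_max` *and* |Spearman correlation of delta vs age| below `rho_max`,
#' ranks ascending by MAE (ties: ascending |rho|, then config_id, then
#' epoch) and returns the first `top_k` (all qualifiers if fewer). The
#' threshold is applied to |rho| because bias correlations are routinely
#' negative.
#'
#' @param records data.frame with columns `config_id`, `epoch`, `val_mae`,
#'   `val_rho`.
#' @param mae_max MAE filter, years (default 3.8).
#' @param rho_max absolute Spearman filter (default 0.1).
#' @param top_k number of checkpoints to keep (default 8).
#' @return the selected rows, in rank order (warns when none qualify).
#' @export
select_checkpoints_objective2 <- function(records, mae_max = 3.8,
                                          rho_max = 0.1, top_k = 8L) {
  if (!nrow(records)) stopf("empty checkpoint pool")
  need <- c("config_id", "epoch", "val_mae", "val_rho")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stopf("records lack column(s): %s", paste(missing, collapse = ", "))
  ok <- records$val_mae < mae_max & abs(records$val_rho) < rho_max
  sel <- records[ok, , drop = FALSE]
  if (!nrow(sel)) {
    warning("no checkpoints satisfy the Objective-2 filters")
    return(sel)
  }
  ord <- order(sel$val_mae, abs(sel$val_rho), sel$config_id, sel$epoch)
  sel <- sel[ord, , drop = FALSE]
  head(sel, top_k)
}
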