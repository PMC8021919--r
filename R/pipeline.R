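# Config-driven orchestration: simulate -> preprocess -> features ->
# train_ml -> train_dl -> ensemble -> evaluate. Every stage writes its
# artifacts under one run directory and registers itself in a manifest;
# one global seed fans out deterministically to per-stage seeds.

#' Default desk-scale pipeline configuration
#'
#' A configuration that exercises the full pipeline in minutes on one CPU:
#' a 60-subject phantom cohort on a 16^3 grid, 24 parcels, 8 ICA components
#' per tissue channel, nested 10-fold CV baselines, and two desk-scale
#' residual-network members (stem width 4) trained for a few epochs. At
#' full scale the published values apply (121x145x121 grid at 1.5 mm, 442
#' parcels, K = 400, stem width 16, 300 epochs); they are reachable by
#' editing the returned list or the equivalent YAML.
#'
#' @param seed global integer seed.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = list(n_subjects = 60L, grid = c(16L, 16L, 16L),
                   n_parcels = 24L, noise_sd = 0.05),
    train_frac = 0.75,
    write_volumes = TRUE,
    parcel_channels = c("gmv", "gmd"),
    sica_channels = c("gmv", "gmd", "wmv", "wmd"),
    sica_K = 8L,
    cv = list(k_outer = 10L, k_inner = 10L),
    dl = list(grid = c(16L, 16L, 16L), stem_width = 4L, epochs = 8L,
              batch_size = 8L, dropout_rate = 0.1,
              members = c("model1-1", "model1-2")),
    objective = 1L,
    ensemble = list(mae_max = 3.8, rho_max = 0.1, top_k = 8L)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_run_config()] (top-level
#' and one level of nesting).
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file.
#' @return configuration list.
#' @export
load_run_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed %||% user$seed %||% 1L)
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(cfg[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else cfg[[k]] <- user[[k]]
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

PIPELINE_STAGES <- c("simulate", "preprocess", "features", "train_ml",
                     "train_dl", "ensemble", "evaluate")

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the brain-age pipeline
#'
#' Executes the requested stages in dependency order under a timestamped
#' run directory; each stage writes its artifacts (tables, metrics,
#' checkpoint records) and appends itself to `manifest.json`. A stage
#' failure halts the run with the stage name in the error; artifacts of
#' completed stages are retained.
#'
#' @param config a [default_run_config()]-shaped list.
#' @param outdir directory under which the run directory is created.
#' @param stages subset of stages to run (prerequisites of a requested
#'   stage are run automatically).
#' @param run_dir optional explicit run directory.
#' @return object of class `pipeline_run`: `dir`, `manifest`, `state`
#'   (in-memory artifacts of the stages that ran).
#' @export
run_pipeline <- function(config = default_run_config(),
                         outdir = tempdir(),
                         stages = PIPELINE_STAGES,
                         run_dir = NULL) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  # a stage needs everything before it
  last <- max(match(stages, PIPELINE_STAGES))
  stages <- PIPELINE_STAGES[seq_len(last)]
  if (is.null(run_dir))
    run_dir <- file.path(outdir, sprintf("run-%s-seed%d",
                                         format(Sys.time(), "%Y%m%d-%H%M%S"),
                                         config$seed))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "brainagekit",
                   version = as.character(utils::packageVersion("brainagekit")),
                   seed = config$seed,
                   config_hash = hash_seed(0, yaml::as.yaml(config)),
                   started = format(Sys.time()), stages = list())
  state <- new.env(parent = emptyenv())
  state$config <- config
  for (st in stages) {
    ok <- tryCatch({
      switch(st,
             simulate = .stage_simulate(state, run_dir),
             preprocess = .stage_preprocess(state, run_dir),
             features = .stage_features(state, run_dir),
             train_ml = .stage_train_ml(state, run_dir),
             train_dl = .stage_train_dl(state, run_dir),
             ensemble = .stage_ensemble(state, run_dir),
             evaluate = .stage_evaluate(state, run_dir))
      TRUE
    }, error = function(e) {
      .write_json(manifest, file.path(run_dir, "manifest.json"))
      stopf("pipeline stage '%s' failed: %s", st, conditionMessage(e))
    })
    manifest$stages[[st]] <- list(status = "complete",
                                  finished = format(Sys.time()))
    .write_json(manifest, file.path(run_dir, "manifest.json"))
  }
  structure(list(dir = run_dir, manifest = manifest, state = state),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline run in %s\n  stages complete: %s\n", x$dir,
              paste(names(x$manifest$stages), collapse = ", ")))
  invisible(x)
}

.stage_simulate <- function(state, run_dir) {
  cfg <- state$config
  ph <- do.call(phantom_config,
                c(cfg$phantom, list(seed = hash_seed(cfg$seed, "phantom"))))
  dir <- if (isTRUE(cfg$write_volumes)) file.path(run_dir, "cohort") else NULL
  state$cohort <- make_cohort(ph, dir = dir)
  if (is.null(dir)) {
    dir.create(file.path(run_dir, "cohort"), showWarnings = FALSE)
    write.csv(state$cohort$records,
              file.path(run_dir, "cohort", "cohort.csv"), row.names = FALSE)
  }
  invisible(TRUE)
}

.stage_preprocess <- function(state, run_dir) {
  cfg <- state$config
  n <- length(state$cohort$volumes)
  idx <- with_seed(hash_seed(cfg$seed, "split"), sample(n))
  n_train <- max(2, round(cfg$train_frac * n))
  state$train_idx <- sort(idx[seq_len(n_train)])
  state$val_idx <- sort(idx[-seq_len(n_train)])
  divisors <- rescale_fit(state$cohort$volumes[state$train_idx])
  state$volumes <- rescale_apply(state$cohort$volumes, divisors)
  state$divisors <- divisors
  .write_json(list(divisors = as.list(divisors),
                   n_train = length(state$train_idx),
                   n_val = length(state$val_idx)),
              file.path(run_dir, "preprocess.json"))
  invisible(TRUE)
}

.stage_features <- function(state, run_dir) {
  cfg <- state$config
  atlas <- state$cohort$atlas
  state$parcel_tab <- build_parcel_table(state$volumes, atlas,
                                         channels = cfg$parcel_channels)
  # ICA convergence status is recorded in the stage artifact rather than
  # surfaced as warnings; the best iterate is still a valid basis.
  bases <- withCallingHandlers(
    fit_sica_bases(state$volumes[state$train_idx],
                   channels = cfg$sica_channels, K = cfg$sica_K,
                   seed = hash_seed(cfg$seed, "sica")),
    warning = function(w) {
      if (grepl("spatial ICA did not converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  state$sica_bases <- bases
  .write_json(list(K = cfg$sica_K,
                   converged = lapply(bases, `[[`, "converged")),
              file.path(run_dir, "sica_fit.json"))
  state$sica_tab <- build_sica_table(state$volumes, bases)
  write.csv(data.frame(subject_id = rownames(state$parcel_tab),
                       state$parcel_tab, check.names = FALSE),
            file.path(run_dir, "parcel_features.csv"), row.names = FALSE)
  write.csv(data.frame(subject_id = rownames(state$sica_tab),
                       state$sica_tab, check.names = FALSE),
            file.path(run_dir, "sica_features.csv"), row.names = FALSE)
  invisible(TRUE)
}

.stage_train_ml <- function(state, run_dir) {
  cfg <- state$config
  ages <- state$cohort$records$age
  tr <- state$train_idx; va <- state$val_idx
  cvc <- cv_config(k_outer = cfg$cv$k_outer, k_inner = cfg$cv$k_inner,
                   seed = hash_seed(cfg$seed, "cv"))
  X <- state$sica_tab
  res <- list()
  for (algo in c("ridge", "svr_rbf")) {
    cv <- nested_cv(X[tr, , drop = FALSE], ages[tr], algo, cvc)
    final <- fit_final(X[tr, , drop = FALSE], ages[tr], algo, cvc)
    res[[algo]] <- list(
      cv = cv, model = final,
      train_pred = predict(final, X[tr, , drop = FALSE]),
      val_pred = predict(final, X[va, , drop = FALSE]))
  }
  state$ml <- res
  .write_json(lapply(res, function(r)
    list(cv_mae = r$cv$mae, cv_rmse = r$cv$rmse, cv_r2 = r$cv$r2,
         chosen = r$cv$chosen, hp_final = r$model$hp)),
    file.path(run_dir, "ml_results.json"))
  preds <- data.frame(subject_id = state$cohort$records$subject_id[va],
                      age = ages[va],
                      ridge = res$ridge$val_pred,
                      svr_rbf = res$svr_rbf$val_pred)
  write.csv(preds, file.path(run_dir, "ml_val_predictions.csv"),
            row.names = FALSE)
  invisible(TRUE)
}

.stage_train_dl <- function(state, run_dir) {
  cfg <- state$config
  ages <- state$cohort$records$age
  sex01 <- as.integer(state$cohort$records$sex == "M")
  tr <- state$train_idx; va <- state$val_idx
  recipes <- objective1_members(names(state$volumes[[1]]$channels),
                                dropout_rate = cfg$dl$dropout_rate)$members
  recipes <- Filter(function(r) r$name %in% cfg$dl$members, recipes)
  if (!length(recipes)) stopf("no DL members selected")
  runs <- list(); records <- list()
  for (r in recipes) {
    x_all <- stack_cohort(state$volumes, r$channels,
                          target_dims = cfg$dl$grid)
    spec <- resnet_spec(length(r$channels), stem_width = cfg$dl$stem_width,
                        dropout_rate = r$dropout_rate,
                        sex_input = r$sex_input)
    model <- resnet_build(spec, seed = hash_seed(cfg$seed, "dl", r$name),
                          input_dims = cfg$dl$grid)
    tc <- train_config(epochs = cfg$dl$epochs,
                       batch_size = cfg$dl$batch_size,
                       loss_mode = r$loss_mode,
                       seed = hash_seed(cfg$seed, "dl-train", r$name))
    fit <- train_resnet(model,
                        x_all[, , , , tr, drop = FALSE], ages[tr],
                        x_all[, , , , va, drop = FALSE], ages[va],
                        config = tc,
                        sex_train = sex01[tr], sex_val = sex01[va],
                        config_id = r$name)
    val_pred <- .resnet_fwd(fit$best_model, x_all[, , , , va, drop = FALSE],
                            sex = sex01[va], training = FALSE)$pred
    runs[[r$name]] <- list(fit = fit, val_pred = val_pred, recipe = r)
    records[[r$name]] <- fit$records
    write.csv(fit$records,
              file.path(run_dir, sprintf("dl_%s_epochs.csv", r$name)),
              row.names = FALSE)
  }
  state$dl <- runs
  state$dl_records <- do.call(rbind, records)
  .write_json(lapply(runs, function(u)
    list(best_epoch = u$fit$best_epoch,
         best_val_mae = min(u$fit$records$val_mae),
         final_val_mae = u$fit$records$val_mae[nrow(u$fit$records)])),
    file.path(run_dir, "dl_results.json"))
  invisible(TRUE)
}

.stage_ensemble <- function(state, run_dir) {
  cfg <- state$config
  pred_matrix <- do.call(rbind, lapply(state$dl, `[[`, "val_pred"))
  state$ensemble_pred <- median_aggregate(pred_matrix)
  sel <- suppressWarnings(
    select_checkpoints_objective2(state$dl_records,
                                  mae_max = cfg$ensemble$mae_max,
                                  rho_max = cfg$ensemble$rho_max,
                                  top_k = cfg$ensemble$top_k))
  state$selection <- sel
  .write_json(list(members = names(state$dl),
                   aggregation = "median",
                   objective2_pool = nrow(state$dl_records),
                   objective2_selected = nrow(sel),
                   selected = sel),
              file.path(run_dir, "ensemble.json"))
  va <- state$val_idx
  write.csv(data.frame(
    subject_id = state$cohort$records$subject_id[va],
    age = state$cohort$records$age[va],
    ensemble = state$ensemble_pred),
    file.path(run_dir, "ensemble_val_predictions.csv"), row.names = FALSE)
  invisible(TRUE)
}

.stage_evaluate <- function(state, run_dir) {
  ages <- state$cohort$records$age
  tr <- state$train_idx; va <- state$val_idx
  reports <- list()
  add <- function(name, pred, train_pred = NULL) {
    b <- prediction_batch(ages[va], pred)
    rep <- metric_report(b)
    out <- list(mae = rep$mae, rmse = rep$rmse, r2 = rep$r2,
                rho = rep$rho, kld = rep$kld)
    if (!is.null(train_pred)) {
      bm <- fit_bias(prediction_batch(ages[tr], train_pred))
      bc <- apply_bias(bm, b)
      repc <- metric_report(bc)
      out$bias <- coef(bm)
      out$corrected <- list(mae = repc$mae, rho = repc$rho)
    }
    reports[[name]] <<- out
  }
  add("ridge", state$ml$ridge$val_pred, state$ml$ridge$train_pred)
  add("svr_rbf", state$ml$svr_rbf$val_pred, state$ml$svr_rbf$train_pred)
  for (nm in names(state$dl)) add(nm, state$dl[[nm]]$val_pred)
  add("ensemble", state$ensemble_pred)
  state$reports <- reports
  .write_json(reports, file.path(run_dir, "metrics.json"))
  invisible(TRUE)
}
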