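# Synthetic age-structured brain phantoms.
#
# The generator emulates a preprocessed structural-MRI cohort: every subject
# gets one pseudo-T1 map, modulated tissue maps (gmv, wmv: "volume"-like),
# unmodulated tissue maps (gmd, wmd: "density"-like) and a stub FLAIR
# channel, on a common grid partitioned into parcels. Within each parcel a
# channel's intensity is an affine function of chronological age plus i.i.d.
# Gaussian voxel noise, so downstream estimators face a known, recoverable
# age signal.

PHANTOM_CHANNELS <- c("t1", "gmv", "wmv", "gmd", "wmd", "flair_stub")

# Per-year intensity change scales per channel. Density channels age faster
# than volume channels so that density-driven models can outperform
# volume-driven ones without asserting that ordering as biology; the stub
# FLAIR channel carries no age signal.
.channel_slope_scale <- c(t1 = -0.0015, gmv = -0.004, wmv = -0.002,
                          gmd = -0.006, wmd = -0.003, flair_stub = 0)
.channel_baseline <- c(t1 = 1.0, gmv = 0.8, wmv = 0.7,
                       gmd = 0.9, wmd = 0.85, flair_stub = 0.6)

#' Configuration for the synthetic phantom cohort
#'
#' Defines the cohort the generator emulates: a right-skewed adult age
#' distribution (truncated log-normal calibrated to the requested mean/SD on
#' \[age_min, age_max\]), a parcellated ellipsoidal "brain", and per-channel,
#' per-parcel age slopes.
#'
#' @param n_subjects number of subjects.
#' @param grid integer vector of 3 voxel counts per axis (all >= 4).
#' @param n_parcels number of parcels tiling the brain mask (>= 2).
#' @param age_mean,age_sd target mean and SD of the age distribution, years.
#' @param age_min,age_max support of the age distribution, years.
#' @param effect_slopes named list (channel -> numeric vector of length
#'   `n_parcels`) of intensity change per year; `NULL` draws deterministic
#'   defaults from `seed`.
#' @param noise_sd SD of additive voxel noise, signal units (>= 0).
#' @param channels channel names to generate.
#' @param voxel_mm voxel edge length, mm.
#' @param seed integer seed; the whole cohort is a pure function of the
#'   config.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects = 120L,
                           grid = c(24L, 28L, 24L),
                           n_parcels = 24L,
                           age_mean = 36.41, age_sd = 16.37,
                           age_min = 17, age_max = 90,
                           effect_slopes = NULL,
                           noise_sd = 0.05,
                           channels = PHANTOM_CHANNELS,
                           voxel_mm = 1.5,
                           seed = 1L) {
  if (!(age_min < age_max)) stopf("age_min must be < age_max")
  if (!is_count(n_parcels) || n_parcels < 2) stopf("n_parcels must be >= 2")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(grid) != 3 || any(grid < 4)) stopf("grid must be 3 axes, each >= 4")
  if (!is_count(n_subjects)) stopf("n_subjects must be a count")
  lp <- .lognormal_params(age_mean, age_sd, age_min, age_max)
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), grid = as.integer(grid),
    n_parcels = as.integer(n_parcels),
    age_mean = age_mean, age_sd = age_sd,
    age_min = age_min, age_max = age_max,
    meanlog = lp[1], sdlog = lp[2],
    noise_sd = noise_sd, channels = channels,
    voxel_mm = voxel_mm, seed = as.integer(seed)
  ), class = "phantom_config")
  cfg$effect_slopes <- effect_slopes %||% .default_slopes(cfg)
  cfg
}

# Solve for (meanlog, sdlog) such that the log-normal truncated to
# [age_min, age_max] has the requested mean and SD.
.lognormal_params <- function(m, s, a, b) {
  moments <- function(p) {
    if (!all(is.finite(p)) || p[2] <= 0) return(c(NA_real_, NA_real_))
    Z <- plnorm(b, p[1], p[2]) - plnorm(a, p[1], p[2])
    if (!is.finite(Z) || Z <= 0) return(c(NA_real_, NA_real_))
    m1 <- integrate(function(x) x * dlnorm(x, p[1], p[2]), a, b)$value / Z
    m2 <- integrate(function(x) x^2 * dlnorm(x, p[1], p[2]), a, b)$value / Z
    c(m1, sqrt(max(m2 - m1^2, 0)))
  }
  s2 <- log(1 + (s / m)^2)
  start <- c(log(m) - s2 / 2, sqrt(s2))
  fit <- optim(start, function(p) {
    mm <- moments(p)
    if (any(!is.finite(mm))) return(1e6)
    sum((mm - c(m, s))^2)
  })
  if (fit$value > 1) stopf("cannot calibrate age distribution to mean %.2f sd %.2f on [%g, %g]",
                           m, s, a, b)
  fit$par
}

.default_slopes <- function(cfg) {
  with_seed(hash_seed(cfg$seed, "slopes"), {
    out <- list()
    for (ch in cfg$channels) {
      scale <- if (ch %in% names(.channel_slope_scale))
        .channel_slope_scale[[ch]] else -0.003
      # per-parcel multiplier in [0.5, 1.5]: every parcel ages, at
      # heterogeneous rates
      out[[ch]] <- scale * runif(cfg$n_parcels, 0.5, 1.5)
    }
    out
  })
}

#' Sample chronological ages
#'
#' Draws `n` ages from the right-skewed truncated log-normal distribution
#' defined by the config (inverse-CDF sampling, so the draw is a
#' deterministic function of the config seed).
#'
#' @param n number of ages to draw.
#' @param config a [phantom_config()].
#' @return numeric vector of ages in `[age_min, age_max]`.
#' @export
sample_ages <- function(n, config) {
  if (!is_count(n)) stopf("n must be a non-negative count")
  if (n == 0) return(numeric(0))
  lo <- plnorm(config$age_min, config$meanlog, config$sdlog)
  hi <- plnorm(config$age_max, config$meanlog, config$sdlog)
  with_seed(hash_seed(config$seed, "ages"), {
    u <- runif(n, lo, hi)
    pmin(pmax(qlnorm(u, config$meanlog, config$sdlog),
              config$age_min), config$age_max)
  })
}

#' Build a parcel atlas on an ellipsoidal brain mask
#'
#' Picks `n_parcels` seed voxels inside an interior ellipsoid and assigns
#' every mask voxel to its nearest seed (ties to the lowest parcel label),
#' yielding contiguous, non-empty parcels labelled 1..n_parcels with
#' background 0.
#'
#' @param grid integer vector of 3 voxel counts.
#' @param n_parcels number of parcels.
#' @param seed integer seed.
#' @return object of class `parcel_atlas` with fields `labels` (3D integer
#'   array), `n_parcels`, `label_ids`, `grid`.
#' @export
make_atlas <- function(grid, n_parcels, seed = 1L) {
  grid <- as.integer(grid)
  mask <- .ellipsoid_mask(grid)
  idx <- which(mask)
  if (n_parcels > length(idx))
    stopf("n_parcels (%d) exceeds mask voxels (%d) for grid %s",
          n_parcels, length(idx), paste(grid, collapse = "x"))
  coords <- arrayInd(idx, .dim = grid)
  centers <- with_seed(hash_seed(seed, "atlas"),
                       coords[sample(nrow(coords), n_parcels), , drop = FALSE])
  # nearest-centroid assignment; ties resolved to the lowest label
  d2 <- outer(rowSums(coords^2), rep(1, n_parcels)) +
    outer(rep(1, nrow(coords)), rowSums(centers^2)) -
    2 * coords %*% t(centers)
  lab <- max.col(-d2, ties.method = "first")
  labels <- array(0L, dim = grid)
  labels[idx] <- lab
  structure(list(labels = labels, n_parcels = as.integer(n_parcels),
                 label_ids = seq_len(n_parcels), grid = grid),
            class = "parcel_atlas")
}

.ellipsoid_mask <- function(grid) {
  ctr <- (grid + 1) / 2
  semi <- pmax((grid - 1) / 2 * 0.92, 1)
  i <- slice.index(array(0, grid), 1)
  j <- slice.index(array(0, grid), 2)
  k <- slice.index(array(0, grid), 3)
  ((i - ctr[1]) / semi[1])^2 + ((j - ctr[2]) / semi[2])^2 +
    ((k - ctr[3]) / semi[3])^2 <= 1
}

# Channel/parcel baseline intensities, a pure function of the config seed.
.baselines <- function(cfg) {
  with_seed(hash_seed(cfg$seed, "baselines"), {
    out <- list()
    for (ch in cfg$channels) {
      base <- if (ch %in% names(.channel_baseline)) .channel_baseline[[ch]] else 1
      out[[ch]] <- base * runif(cfg$n_parcels, 0.9, 1.1)
    }
    out
  })
}

#' Render one subject's multichannel phantom volume
#'
#' Voxel values inside parcel p of channel c are
#' `baseline(c, p) + slope(c, p) * (age - age_mean) + N(0, noise_sd)`;
#' background voxels are 0. The noise stream depends only on
#' `(config seed, subject_id)`, so cohorts are order-independent.
#'
#' @param record list or one-row data.frame with `subject_id` and `age`.
#' @param atlas a [make_atlas()] result on the config grid.
#' @param config a [phantom_config()].
#' @return object of class `subject_volume`: `subject_id`, named list
#'   `channels` of 3D arrays, `voxel_mm`.
#' @export
render_subject <- function(record, atlas, config) {
  if (!identical(dim(atlas$labels), as.integer(config$grid)))
    stopf("atlas grid does not match config grid")
  age <- record$age
  baselines <- .baselines(config)
  idx_by_parcel <- split(which(atlas$labels > 0),
                         atlas$labels[atlas$labels > 0])
  mask_idx <- which(atlas$labels > 0)
  chans <- with_seed(hash_seed(config$seed, "subject", record$subject_id), {
    out <- list()
    for (ch in config$channels) {
      vol <- array(0, dim = config$grid)
      for (p in seq_len(config$n_parcels)) {
        mu <- baselines[[ch]][p] +
          config$effect_slopes[[ch]][p] * (age - config$age_mean)
        vol[idx_by_parcel[[as.character(p)]]] <- mu
      }
      if (config$noise_sd > 0)
        vol[mask_idx] <- vol[mask_idx] +
          rnorm(length(mask_idx), 0, config$noise_sd)
      out[[ch]] <- vol
    }
    out
  })
  structure(list(subject_id = record$subject_id, channels = chans,
                 voxel_mm = rep(config$voxel_mm, 3)),
            class = "subject_volume")
}

#' Generate a full phantom cohort
#'
#' Samples ages and sex, builds the atlas, renders every subject, and
#' optionally writes the cohort to disk (one 4D NIfTI per subject, the atlas
#' as NIfTI, and `cohort.csv` with subject_id, age, sex).
#'
#' @param config a [phantom_config()].
#' @param dir optional output directory.
#' @return list with `volumes` (list of `subject_volume`), `records`
#'   (data.frame subject_id, age, sex), `atlas`, `config`.
#' @export
make_cohort <- function(config, dir = NULL) {
  n <- config$n_subjects
  ages <- sample_ages(n, config)
  sex <- with_seed(hash_seed(config$seed, "sex"),
                   sample(c("M", "F"), n, replace = TRUE,
                          prob = c(0.463, 0.537)))
  records <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    age = ages, sex = sex, stringsAsFactors = FALSE)
  atlas <- make_atlas(config$grid, config$n_parcels,
                      seed = hash_seed(config$seed, "atlas-top"))
  volumes <- lapply(seq_len(n), function(i)
    render_subject(records[i, ], atlas, config))
  cohort <- list(volumes = volumes, records = records,
                 atlas = atlas, config = config)
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a cohort to disk
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tryCatch({
    write.csv(cohort$records, file.path(dir, "cohort.csv"), row.names = FALSE)
    RNifti::writeNifti(.as_nifti(cohort$atlas$labels, cohort$config$voxel_mm),
                       file.path(dir, "atlas.nii.gz"))
    for (sv in cohort$volumes) {
      arr <- .stack4d(sv)
      RNifti::writeNifti(.as_nifti(arr, cohort$config$voxel_mm),
                         file.path(dir, paste0(sv$subject_id, ".nii.gz")))
    }
  }, error = function(e) stopf("failed writing cohort to %s: %s",
                               dir, conditionMessage(e)))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param channels channel names in the order they were stacked.
#' @return list with `volumes`, `records`, `atlas_labels`.
#' @export
read_cohort <- function(dir, channels = PHANTOM_CHANNELS) {
  csv <- file.path(dir, "cohort.csv")
  if (!file.exists(csv)) stopf("no cohort.csv under %s", dir)
  records <- read.csv(csv, stringsAsFactors = FALSE)
  atlas_labels <- NULL
  af <- file.path(dir, "atlas.nii.gz")
  if (file.exists(af)) {
    img <- RNifti::readNifti(af)
    atlas_labels <- array(as.integer(round(img)), dim = dim(img))
  }
  volumes <- lapply(records$subject_id, function(sid) {
    f <- file.path(dir, paste0(sid, ".nii.gz"))
    if (!file.exists(f)) stopf("missing volume file %s", f)
    img <- RNifti::readNifti(f)
    arr <- array(as.numeric(img), dim = dim(img))
    vox <- RNifti::pixdim(img)[1:3]
    chans <- lapply(seq_len(dim(arr)[4]), function(c4) arr[, , , c4])
    names(chans) <- channels[seq_len(dim(arr)[4])]
    structure(list(subject_id = sid, channels = chans, voxel_mm = vox),
              class = "subject_volume")
  })
  list(volumes = volumes, records = records, atlas_labels = atlas_labels)
}

.stack4d <- function(sv) {
  d <- dim(sv$channels[[1]])
  arr <- array(0, dim = c(d, length(sv$channels)))
  for (i in seq_along(sv$channels)) arr[, , , i] <- sv$channels[[i]]
  arr
}

.as_nifti <- function(arr, voxel_mm) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(voxel_mm, 3), rep(1, length(dim(arr)) - 3))
  img
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("phantom_config: %d subjects, grid %s, %d parcels\n",
              x$n_subjects, paste(x$grid, collapse = "x"), x$n_parcels))
  cat(sprintf("  ages ~ truncated log-normal, target mean %.2f sd %.2f on [%g, %g]\n",
              x$age_mean, x$age_sd, x$age_min, x$age_max))
  cat(sprintf("  channels: %s; noise sd %.3g; seed %d\n",
              paste(x$channels, collapse = ", "), x$noise_sd, x$seed))
  invisible(x)
}
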