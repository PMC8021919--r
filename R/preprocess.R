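# Input preprocessing: [0,1] intensity rescaling by the training-set
# maximum, grid conformation by trilinear resampling, and 4D channel
# stacking.

#' Fit per-channel rescaling divisors on a training cohort
#'
#' The divisor for a channel is the maximum voxel value over *all training
#' subjects*; dividing by it maps the training data into \[0, 1\]. The fitted
#' divisors must be re-applied (not re-fit) to validation/test subjects, so
#' no information leaks across the split.
#'
#' @param volumes list of `subject_volume` (training subjects only).
#' @param channels channels to fit; default all channels of the first
#'   subject.
#' @return named numeric vector of divisors.
#' @export
rescale_fit <- function(volumes, channels = NULL) {
  if (length(volumes) < 1) stopf("need at least one training subject")
  channels <- channels %||% names(volumes[[1]]$channels)
  div <- vapply(channels, function(ch) {
    max(vapply(volumes, function(sv) {
      if (is.null(sv$channels[[ch]])) stopf("channel '%s' missing", ch)
      max(sv$channels[[ch]])
    }, numeric(1)))
  }, numeric(1))
  bad <- names(div)[div <= 0]
  if (length(bad))
    stopf("degenerate input: channel(s) %s have non-positive training maximum",
          paste(bad, collapse = ", "))
  div
}

#' Apply fitted rescaling divisors to a cohort
#'
#' Divides every voxel by the stored per-channel training maximum. Values
#' above the training maximum (possible on validation/test subjects) are
#' clipped to 1 so the \[0, 1\] contract holds everywhere.
#'
#' @param volumes list of `subject_volume`.
#' @param divisors named vector from [rescale_fit()].
#' @param clip clip to \[0, 1\] after division (default TRUE).
#' @return the volumes, rescaled.
#' @export
rescale_apply <- function(volumes, divisors, clip = TRUE) {
  lapply(volumes, function(sv) {
    for (ch in names(divisors)) {
      v <- sv$channels[[ch]] / divisors[[ch]]
      if (clip) v <- pmin(pmax(v, 0), 1)
      sv$channels[[ch]] <- v
    }
    sv
  })
}

#' Rescale a training cohort to \[0, 1\]
#'
#' Convenience wrapper: fits divisors on the given (training) volumes and
#' applies them.
#'
#' @inheritParams rescale_fit
#' @return list with `volumes` (rescaled) and `divisors`.
#' @export
rescale_cohort <- function(volumes, channels = NULL) {
  divisors <- rescale_fit(volumes, channels)
  list(volumes = rescale_apply(volumes, divisors), divisors = divisors)
}

#' Resample a volume onto a target grid by trilinear interpolation
#'
#' Voxel centers are aligned in physical space: target voxel centre
#' coordinates are mapped into the source index space given both voxel
#' sizes, interpolated trilinearly, and padded with 0 outside the source
#' field of view. With `target_voxel_mm = NULL` the target voxel size is
#' chosen so the physical field of view is preserved (a pure resize).
#'
#' @param volume 3D numeric array.
#' @param target_dims integer vector of 3 target voxel counts.
#' @param target_voxel_mm target voxel size (scalar or length 3), or NULL.
#' @param voxel_mm source voxel size (scalar or length 3), default 1.
#' @return 3D array of dim `target_dims`.
#' @export
conform_grid <- function(volume, target_dims, target_voxel_mm = NULL,
                         voxel_mm = 1) {
  target_dims <- as.integer(target_dims)
  if (length(target_dims) != 3 || any(target_dims < 1))
    stopf("target_dims must be 3 positive integers")
  src_dims <- dim(volume)
  voxel_mm <- rep(voxel_mm, length.out = 3)
  target_voxel_mm <- rep(target_voxel_mm %||%
                           (src_dims * voxel_mm / target_dims),
                         length.out = 3)
  if (identical(src_dims, target_dims) &&
      isTRUE(all.equal(target_voxel_mm, voxel_mm))) return(volume)
  # physical coordinate of target voxel centre -> fractional source index
  src_of <- lapply(1:3, function(a) {
    ((seq_len(target_dims[a]) - 0.5) * target_voxel_mm[a]) / voxel_mm[a] + 0.5
  })
  gx <- rep(src_of[[1]], times = target_dims[2] * target_dims[3])
  gy <- rep(rep(src_of[[2]], each = target_dims[1]), times = target_dims[3])
  gz <- rep(src_of[[3]], each = target_dims[1] * target_dims[2])
  x0 <- floor(gx); y0 <- floor(gy); z0 <- floor(gz)
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  out <- numeric(prod(target_dims))
  # zero-padded lookup of the source array at integer indices
  look <- function(i, j, k) {
    ok <- i >= 1 & i <= src_dims[1] & j >= 1 & j <= src_dims[2] &
      k >= 1 & k <= src_dims[3]
    v <- numeric(length(i))
    v[ok] <- volume[cbind(i[ok], j[ok], k[ok])]
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    nz <- w > 0
    if (any(nz))
      out[nz] <- out[nz] + w[nz] *
        look(x0[nz] + dx, y0[nz] + dy, z0[nz] + dz)
  }
  array(out, dim = target_dims)
}

#' Stack a subject's channels into a 4D input
#'
#' Concatenates the named channels, in the configured order, into a
#' `(channel, x, y, z)` array: the single-subject slice of the 4D input
#' structure consumed by the convolutional regressor.
#'
#' @param subject a `subject_volume`.
#' @param channel_names channels to stack, in order.
#' @return 4D array of dim `(n_channels, nx, ny, nz)` with attribute
#'   `channel_names`.
#' @export
stack_channels <- function(subject, channel_names) {
  missing <- setdiff(channel_names, names(subject$channels))
  if (length(missing))
    stopf("subject %s is missing channel(s): %s",
          subject$subject_id %||% "?", paste(missing, collapse = ", "))
  dims <- dim(subject$channels[[channel_names[1]]])
  arr <- array(0, dim = c(dims, length(channel_names)))
  for (i in seq_along(channel_names)) {
    ch <- subject$channels[[channel_names[i]]]
    if (!identical(dim(ch), dims)) stopf("channel grids differ")
    arr[, , , i] <- ch
  }
  out <- aperm(arr, c(4, 1, 2, 3))
  attr(out, "channel_names") <- channel_names
  out
}

# Stack a whole cohort into the (x, y, z, channel, subject) layout used by
# the network internals.
stack_cohort <- function(volumes, channel_names, target_dims = NULL) {
  n <- length(volumes)
  dims <- dim(volumes[[1]]$channels[[channel_names[1]]])
  if (!is.null(target_dims)) dims <- as.integer(target_dims)
  x <- array(0, dim = c(dims, length(channel_names), n))
  for (s in seq_len(n)) {
    for (ci in seq_along(channel_names)) {
      v <- volumes[[s]]$channels[[channel_names[ci]]]
      if (is.null(v)) stopf("subject %s missing channel '%s'",
                            volumes[[s]]$subject_id, channel_names[ci])
      if (!is.null(target_dims) && !identical(dim(v), dims))
        v <- conform_grid(v, dims, voxel_mm = volumes[[s]]$voxel_mm[1])
      x[, , , ci, s] <- v
    }
  }
  x
}
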