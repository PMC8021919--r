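# Feature extraction for the conventional ML baselines:
#  * parcel-wise means over an integer-labelled atlas, and
#  * spatial-ICA component bases with per-subject "integrity scores" (beta
#    weights from a joint spatial regression), the dual-regression
#    convention.

#' Parcel-wise mean features for one volume
#'
#' @param volume 3D numeric array.
#' @param atlas a `parcel_atlas` (or a 3D integer label array) on the same
#'   grid; label 0 is background.
#' @return numeric vector, one mean per label id in ascending label order.
#' @export
parcel_means <- function(volume, atlas) {
  labels <- if (inherits(atlas, "parcel_atlas")) atlas$labels else atlas
  if (!identical(dim(volume), dim(labels))) stopf("volume/atlas grids differ")
  lab <- as.vector(labels)
  keep <- lab > 0
  label_ids <- if (inherits(atlas, "parcel_atlas")) atlas$label_ids else
    sort(unique(lab[keep]))
  sums <- rowsum(as.vector(volume)[keep], lab[keep])
  counts <- rowsum(rep(1, sum(keep)), lab[keep])
  present <- as.integer(rownames(sums))
  if (!all(label_ids %in% present))
    stopf("empty parcel(s): %s",
          paste(setdiff(label_ids, present), collapse = ", "))
  m <- (sums / counts)[match(label_ids, present), 1]
  assert_finite(m, "parcel means")
  m
}

#' Parcel-wise feature table for a cohort
#'
#' One row per subject; columns are `<channel>_p<label>` for each requested
#' channel in order, each parcel in ascending label order (so a 442-parcel
#' atlas with 2 channels yields 884 columns).
#'
#' @param volumes list of `subject_volume`.
#' @param atlas a `parcel_atlas`.
#' @param channels channels to extract.
#' @return object of class `feature_table`: numeric matrix with rownames =
#'   subject ids.
#' @export
build_parcel_table <- function(volumes, atlas, channels = c("gmv", "gmd")) {
  rows <- lapply(volumes, function(sv) {
    unlist(lapply(channels, function(ch) {
      if (is.null(sv$channels[[ch]])) stopf("channel '%s' missing", ch)
      parcel_means(sv$channels[[ch]], atlas)
    }))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- as.vector(outer(atlas$label_ids, channels,
                                 function(p, ch) sprintf("%s_p%03d", ch, p)))
  rownames(m) <- vapply(volumes, `[[`, character(1), "subject_id")
  assert_finite(m, "parcel feature table")
  structure(m, class = c("feature_table", class(m)))
}

#' Voxel inclusion mask for spatial ICA
#'
#' Keeps voxels that are nonzero in at least `min_frac` of the training
#' subjects for the given channel.
#'
#' @param volumes training `subject_volume` list.
#' @param channel channel name.
#' @param min_frac inclusion fraction (default 0.95).
#' @return logical 3D array.
#' @export
make_mask <- function(volumes, channel, min_frac = 0.95) {
  nz <- Reduce(`+`, lapply(volumes, function(sv)
    (sv$channels[[channel]] != 0) * 1))
  nz / length(volumes) >= min_frac
}

#' Fit a spatial-ICA component basis
#'
#' Decomposes a subjects-by-voxels data matrix into `K` spatially
#' independent component maps: voxel-wise centering, PCA whitening to `K`
#' dimensions, then symmetric FastICA with the logcosh contrast. Component
#' sign is fixed so each map has positive skewness; the whole fit is a
#' deterministic function of `seed` (component order, like any ICA, is
#' otherwise arbitrary).
#'
#' @param X numeric matrix, subjects x masked voxels.
#' @param K number of components (<= number of subjects).
#' @param seed integer seed for the orthogonal initialization.
#' @param mask optional logical 3D array the columns of `X` correspond to.
#' @param maxit,tol FastICA iteration controls.
#' @return object of class `component_basis`: `maps` (K x voxels, each row
#'   a unit-variance spatial component), `mask`, `K`, `center` (voxel
#'   means), `converged`.
#' @export
fit_spatial_ica <- function(X, K, seed = 1L, mask = NULL,
                            maxit = 500L, tol = 1e-4) {
  n <- nrow(X); V <- ncol(X)
  if (K > n) stopf("K (%d) exceeds number of subjects (%d)", K, n)
  if (V < 1) stopf("mask is empty")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = K, nv = 0)
  if (sv$d[K] < 1e-12 * sv$d[1])
    stopf("data rank below K = %d; reduce K", K)
  # principal spatial maps, rows scaled to unit variance over voxels
  P <- crossprod(sv$u, Xc) / sv$d[1:K]          # K x V, orthonormal rows
  Pw <- P * sqrt(V)                             # unit-variance rows
  W <- with_seed(hash_seed(seed, "ica-init"), {
    M <- matrix(rnorm(K * K), K, K)
    qr.Q(qr(M))
  })
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), K) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  best_delta <- Inf; W_best <- W
  for (it in seq_len(maxit)) {
    S <- W %*% Pw                               # K x V current sources
    G <- tanh(S)
    Gp <- rowMeans(1 - G^2)                     # E[g'(s)]
    W_new <- (G %*% t(Pw)) / V - diag(Gp, K) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < best_delta) { best_delta <- delta; W_best <- W }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    W <- W_best
    warning(sprintf("spatial ICA did not converge in %d iterations (best step change %.2g); returning best iterate",
                    maxit, best_delta))
  }
  maps <- W %*% Pw
  # deterministic orientation: positive skewness per component
  sk <- rowMeans(maps^3)
  maps <- maps * ifelse(sk < 0, -1, 1)
  structure(list(maps = maps, mask = mask, K = as.integer(K),
                 center = center, converged = converged),
            class = "component_basis")
}

#' Integrity scores: joint spatial regression on a component basis
#'
#' Regresses one subject's (masked) voxel vector on all `K` component maps
#' jointly, with an intercept; the returned beta weights are the subject's
#' integrity scores.
#'
#' @param subject_map numeric vector of the subject's masked voxels (or a 3D
#'   array when the basis carries a mask).
#' @param basis a [fit_spatial_ica()] result.
#' @return numeric vector of `K` betas.
#' @export
integrity_scores <- function(subject_map, basis) {
  if (is.array(subject_map) && length(dim(subject_map)) == 3) {
    if (is.null(basis$mask)) stopf("basis has no mask to apply to a volume")
    subject_map <- subject_map[basis$mask]
  }
  v <- as.numeric(subject_map)
  if (length(v) != ncol(basis$maps))
    stopf("subject map length (%d) does not conform to basis voxels (%d)",
          length(v), ncol(basis$maps))
  design <- cbind(intercept = 1, t(basis$maps))
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    drop <- setdiff(seq_len(ncol(design)), qd$pivot[seq_len(qd$rank)])
    stopf("rank-deficient spatial regression; collinear columns: %s",
          paste(colnames(design)[drop] %||% (drop - 1L), collapse = ", "))
  }
  as.numeric(qr.coef(qd, v))[-1]
}

#' Spatial-ICA feature table for a cohort
#'
#' Fits nothing: applies per-channel frozen bases (fit on training subjects)
#' to every subject, concatenating the `K` betas of each channel, so `K`
#' components over 4 tissue feature sets yield `4 K` columns.
#'
#' @param volumes list of `subject_volume`.
#' @param bases named list (channel -> `component_basis`).
#' @return object of class `feature_table`, columns `<channel>_ic<k>`.
#' @export
build_sica_table <- function(volumes, bases) {
  rows <- lapply(volumes, function(sv) {
    unlist(lapply(names(bases), function(ch) {
      vol <- sv$channels[[ch]]
      if (is.null(vol)) stopf("channel '%s' missing for %s", ch, sv$subject_id)
      integrity_scores(vol, bases[[ch]])
    }))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- unlist(lapply(names(bases), function(ch)
    sprintf("%s_ic%03d", ch, seq_len(bases[[ch]]$K))))
  rownames(m) <- vapply(volumes, `[[`, character(1), "subject_id")
  assert_finite(m, "sICA feature table")
  structure(m, class = c("feature_table", class(m)))
}

#' Fit spatial-ICA bases for several channels on training subjects
#'
#' For each channel: build the training mask, assemble the subjects x
#' masked-voxels matrix, and fit the ICA basis. Bases must be fit on
#' training subjects only and then applied, frozen, to held-out subjects.
#'
#' @param volumes training `subject_volume` list.
#' @param channels channels to decompose.
#' @param K components per channel.
#' @param seed integer seed.
#' @param min_frac mask inclusion fraction, see [make_mask()].
#' @return named list of `component_basis`.
#' @export
fit_sica_bases <- function(volumes, channels = c("gmv", "gmd", "wmv", "wmd"),
                           K = 20L, seed = 1L, min_frac = 0.95) {
  out <- list()
  for (ch in channels) {
    mask <- make_mask(volumes, ch, min_frac)
    X <- do.call(rbind, lapply(volumes, function(sv) sv$channels[[ch]][mask]))
    out[[ch]] <- fit_spatial_ica(X, K, seed = hash_seed(seed, "ica", ch),
                                 mask = mask)
  }
  out
}
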