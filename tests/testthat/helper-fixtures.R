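# Shared fixtures and independent oracles for the test suite.

# Minimal subject_volume constructor for hand-built inputs.
make_sv <- function(channels, subject_id = "sub-test", voxel_mm = 1) {
  structure(list(subject_id = subject_id, channels = channels,
                 voxel_mm = rep(voxel_mm, 3)),
            class = "subject_volume")
}

# Independent double-loop oracles for the two regularization losses.
cov_loss_brute <- function(y, y_pred) {
  n <- length(y)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    total <- total + ((y_pred[i] - y[i]) * y[j])^2
  total / n
}

rank_loss_brute <- function(y, y_pred) {
  n <- length(y)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    total <- total + (y_pred[i] * y_pred[j] - y[i] * y[j])^2
  total / n
}

# Central finite-difference gradient of f at x.
fd_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# A small cohort used by several test files; built once per test run.
tiny_cohort <- function(n = 12, grid = c(12, 12, 12), n_parcels = 8,
                        noise_sd = 0.05, seed = 101) {
  make_cohort(phantom_config(n_subjects = n, grid = grid,
                             n_parcels = n_parcels, noise_sd = noise_sd,
                             seed = seed))
}

# Plant k spatially disjoint sources in a 3D grid and mix them across
# subjects: the ground truth for ICA recovery tests.
planted_source_phantoms <- function(n = 60, grid = c(12, 12, 12), k = 3,
                                    noise_sd = 0.05, seed = 7) {
  set.seed(seed)
  V <- prod(grid)
  centers <- list(c(4, 4, 4), c(9, 9, 5), c(5, 9, 9))[seq_len(k)]
  S <- matrix(0, k, V)
  coords <- arrayInd(seq_len(V), grid)
  for (s in seq_len(k)) {
    d2 <- rowSums(sweep(coords, 2, centers[[s]])^2)
    S[s, d2 <= 6] <- 2
  }
  A <- matrix(rnorm(n * k), n, k)
  X <- A %*% S + matrix(rnorm(n * V, 0, noise_sd), n, V)
  list(X = X, sources = S, mixing = A, grid = grid)
}
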