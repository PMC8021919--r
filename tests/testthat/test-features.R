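test_that("parcel means match hand computation and are linear", {
  labels <- array(0L, c(5, 1, 1))
  labels[1:2] <- 1L; labels[3:5] <- 2L
  vol <- array(c(1, 3, 2, 2, 2), c(5, 1, 1))
  expect_equal(parcel_means(vol, labels), c(`1` = 2, `2` = 2))
  const <- array(3, c(5, 1, 1))
  expect_equal(unname(parcel_means(const, labels)), c(3, 3))
  # linearity: means(aX + bY) = a means(X) + b means(Y)
  set.seed(2)
  at <- make_atlas(c(8, 8, 8), 4, seed = 3)
  X <- array(rnorm(512), c(8, 8, 8)); Y <- array(rnorm(512), c(8, 8, 8))
  expect_equal(parcel_means(2 * X - 3 * Y, at),
               2 * parcel_means(X, at) - 3 * parcel_means(Y, at),
               tolerance = 1e-12)
})

test_that("a 442-parcel atlas with two channels yields 884 features", {
  at <- make_atlas(c(16, 16, 16), 442, seed = 1)
  cfg <- phantom_config(n_subjects = 2, grid = c(16, 16, 16),
                        n_parcels = 442, channels = c("gmv", "gmd"),
                        seed = 8)
  co <- make_cohort(cfg)
  tab <- build_parcel_table(co$volumes, at, channels = c("gmv", "gmd"))
  expect_identical(dim(tab), c(2L, 884L))
  expect_identical(colnames(tab)[1], "gmv_p001")
  expect_identical(colnames(tab)[884], "gmd_p442")
})

test_that("spatial ICA recovers planted disjoint sources", {
  ph <- planted_source_phantoms(n = 60, k = 3, noise_sd = 0.05)
  basis <- fit_spatial_ica(ph$X, 3, seed = 1)
  cc <- abs(cor(t(basis$maps), t(ph$sources)))
  # each true source matches a distinct component, up to sign/permutation
  best <- apply(cc, 2, max)
  expect_true(all(best > 0.95))
  expect_identical(length(unique(apply(cc, 2, which.max))), 3L)
  # seed determinism
  basis2 <- fit_spatial_ica(ph$X, 3, seed = 1)
  expect_identical(basis$maps, basis2$maps)
})

test_that("rank-1 data gives back its single spatial pattern", {
  set.seed(5)
  s <- rnorm(300)^3                       # non-Gaussian spatial pattern
  X <- outer(rnorm(20), s) + matrix(rnorm(20 * 300, 0, 1e-3), 20)
  basis <- fit_spatial_ica(X, 1, seed = 2)
  expect_gt(abs(cor(as.numeric(basis$maps), s)), 0.999)
})

test_that("ICA rejects K above the available rank", {
  X <- matrix(rnorm(5 * 50), 5, 50)
  expect_error(fit_spatial_ica(X, 6, seed = 1), "exceeds")
})

test_that("integrity scores equal the normal-equations oracle", {
  set.seed(9)
  K <- 6; V <- 400
  maps <- matrix(rnorm(K * V), K, V)
  basis <- structure(list(maps = maps, mask = NULL, K = K,
                          center = rep(0, V), converged = TRUE),
                     class = "component_basis")
  y <- rnorm(V)
  betas <- integrity_scores(y, basis)
  D <- cbind(1, t(maps))
  oracle <- solve(crossprod(D), crossprod(D, y))[-1]
  expect_lt(max(abs(betas - oracle)), 1e-8)
})

test_that("integrity scores round-trip constructed mixtures", {
  set.seed(10)
  # orthogonal maps: exact recovery of planted weights
  Q <- qr.Q(qr(matrix(rnorm(200 * 3), 200, 3)))
  basis <- structure(list(maps = t(Q), mask = NULL, K = 3,
                          center = rep(0, 200), converged = TRUE),
                     class = "component_basis")
  expect_lt(max(abs(integrity_scores(2 * Q[, 1], basis) - c(2, 0, 0))), 1e-8)
  # noise orthogonal to every map (and the intercept): zero betas
  noise <- rnorm(200)
  D <- cbind(1, Q)
  noise <- noise - D %*% solve(crossprod(D), crossprod(D, noise))
  expect_lt(max(abs(integrity_scores(as.numeric(noise), basis))), 1e-8)
  # random weights through a non-orthogonal basis
  maps <- matrix(rnorm(5 * 300), 5, 300)
  basis2 <- structure(list(maps = maps, mask = NULL, K = 5,
                           center = rep(0, 300), converged = TRUE),
                      class = "component_basis")
  w <- runif(5, -2, 2)
  got <- integrity_scores(as.numeric(t(maps) %*% w), basis2)
  expect_lt(max(abs(got - w)), 1e-6)
})

test_that("collinear component maps are reported as an error", {
  maps <- matrix(rnorm(3 * 100), 3, 100)
  maps[3, ] <- 2 * maps[1, ]
  basis <- structure(list(maps = maps, mask = NULL, K = 3,
                          center = rep(0, 100), converged = TRUE),
                     class = "component_basis")
  expect_error(integrity_scores(rnorm(100), basis), "collinear")
})

test_that("sICA tables have K x n_sets columns with a naming bijection", {
  co <- tiny_cohort(n = 10)
  tr <- co$volumes[1:8]
  bases <- suppressWarnings(
    fit_sica_bases(tr, channels = c("gmv", "gmd"), K = 5, seed = 3))
  tab <- build_sica_table(co$volumes, bases)
  expect_identical(dim(tab), c(10L, 10L))
  parsed <- do.call(rbind, strsplit(colnames(tab), "_ic"))
  expect_identical(anyDuplicated(colnames(tab)), 0L)
  expect_setequal(unique(parsed[, 1]), c("gmv", "gmd"))
  # shape arithmetic at full scale: K = 400 over 4 sets -> 1600 columns
  fake <- lapply(c("gmv", "gmd", "wmv", "wmd"), function(ch)
    structure(list(maps = matrix(rnorm(400 * 450), 400, 450), mask = NULL,
                   K = 400L, center = rep(0, 450), converged = TRUE),
              class = "component_basis"))
  names(fake) <- c("gmv", "gmd", "wmv", "wmd")
  nm <- unlist(lapply(names(fake), function(ch)
    sprintf("%s_ic%03d", ch, seq_len(fake[[ch]]$K))))
  expect_identical(length(nm), 1600L)
})

test_that("the training mask keeps voxels present in most subjects", {
  grid <- c(4, 4, 4)
  mk <- function(z) make_sv(list(gmv = array(z, grid)))
  vols <- list(mk(1), mk(1), mk(1))
  vols[[1]]$channels$gmv[1] <- 0    # voxel 1 present in 2/3 subjects
  m <- make_mask(vols, "gmv", min_frac = 0.95)
  expect_false(m[1])
  expect_true(all(m[-1]))
})
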