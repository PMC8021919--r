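test_that("sampled ages reproduce the cohort moments and support", {
  cfg <- phantom_config(seed = 3)
  expect_identical(sample_ages(0, cfg), numeric(0))
  a <- sample_ages(2483, cfg)
  expect_true(all(a >= 17 & a <= 90))
  expect_lt(abs(mean(a) - 36.41), 2.0)
  expect_lt(abs(sd(a) - 16.37), 2.0)
  # right skew: mean above median
  expect_gt(mean(a), median(a))
  expect_identical(sample_ages(1000, cfg), sample_ages(1000, cfg))
})

test_that("age distribution calibration adapts to other target moments", {
  cfg <- phantom_config(age_mean = 50, age_sd = 10, seed = 4)
  a <- sample_ages(5000, cfg)
  expect_lt(abs(mean(a) - 50), 1.5)
  expect_lt(abs(sd(a) - 10), 1.5)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(age_min = 90, age_max = 17), "age_min")
  expect_error(phantom_config(n_parcels = 1), "n_parcels")
  expect_error(phantom_config(noise_sd = -1), "noise_sd")
})

test_that("atlas parcels tile the mask with complete non-empty labels", {
  at <- make_atlas(c(8, 8, 8), 2, seed = 1)
  expect_setequal(unique(as.vector(at$labels)), c(0L, 1L, 2L))
  at442 <- make_atlas(c(16, 16, 16), 442, seed = 1)
  expect_identical(length(unique(at442$labels[at442$labels > 0])), 442L)
  expect_identical(make_atlas(c(8, 8, 8), 5, seed = 9)$labels,
                   make_atlas(c(8, 8, 8), 5, seed = 9)$labels)
  expect_error(make_atlas(c(4, 4, 4), 500, seed = 1), "exceeds")
})

test_that("noise-free rendering is an exact affine function of age", {
  grid <- c(8, 8, 8)
  slopes <- list(gmv = c(-0.5, 0))
  cfg <- phantom_config(n_subjects = 2, grid = grid, n_parcels = 2,
                        effect_slopes = slopes, noise_sd = 0,
                        channels = "gmv", seed = 5)
  atlas <- make_atlas(grid, 2, seed = 2)
  v30 <- render_subject(list(subject_id = "a", age = 30), atlas, cfg)
  v40 <- render_subject(list(subject_id = "b", age = 40), atlas, cfg)
  m30 <- parcel_means(v30$channels$gmv, atlas)
  m40 <- parcel_means(v40$channels$gmv, atlas)
  expect_equal(unname(m40[1] - m30[1]), -5.0, tolerance = 1e-12)
  expect_equal(unname(m40[2]), unname(m30[2]), tolerance = 1e-12)
  # all-zero slopes: identical volumes across ages
  cfg0 <- phantom_config(n_subjects = 2, grid = grid, n_parcels = 2,
                         effect_slopes = list(gmv = c(0, 0)), noise_sd = 0,
                         channels = "gmv", seed = 5)
  va <- render_subject(list(subject_id = "a", age = 20), atlas, cfg0)
  vb <- render_subject(list(subject_id = "a", age = 80), atlas, cfg0)
  expect_identical(va$channels$gmv, vb$channels$gmv)
})

test_that("regression on a noisy cohort recovers the generating slope", {
  grid <- c(10, 10, 10)
  slopes <- list(gmv = c(-0.02, 0.01, 0))
  cfg <- phantom_config(n_subjects = 200, grid = grid, n_parcels = 3,
                        effect_slopes = slopes, noise_sd = 0.1,
                        channels = "gmv", seed = 11)
  co <- make_cohort(cfg)
  m1 <- vapply(co$volumes, function(sv)
    parcel_means(sv$channels$gmv, co$atlas)[1], numeric(1))
  fit <- summary(lm(m1 ~ co$records$age))
  est <- fit$coefficients[2, 1]; se <- fit$coefficients[2, 2]
  expect_lt(abs(est - (-0.02)), 3 * se)
})

test_that("cohort generation is seed-deterministic and order-independent", {
  cfg <- phantom_config(n_subjects = 4, grid = c(8, 8, 8), n_parcels = 3,
                        seed = 21)
  co1 <- make_cohort(cfg)
  co2 <- make_cohort(cfg)
  expect_identical(co1$records, co2$records)
  expect_identical(co1$volumes[[3]]$channels, co2$volumes[[3]]$channels)
  # a subject rendered in isolation matches its in-cohort rendering
  solo <- render_subject(co1$records[2, ], co1$atlas, cfg)
  expect_identical(solo$channels, co1$volumes[[2]]$channels)
})

test_that("a cohort round-trips through NIfTI and CSV", {
  cfg <- phantom_config(n_subjects = 3, grid = c(8, 8, 8), n_parcels = 3,
                        channels = c("t1", "gmv"), seed = 31)
  co <- make_cohort(cfg)
  co$records$age <- as.numeric(round(co$records$age))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir, channels = c("t1", "gmv"))
  expect_identical(as.numeric(back$records$age), co$records$age)
  expect_identical(back$records$subject_id, co$records$subject_id)
  expect_lt(max(abs(back$volumes[[2]]$channels$gmv -
                      co$volumes[[2]]$channels$gmv)), 1e-6)
  expect_identical(back$atlas_labels, co$atlas$labels)
})
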