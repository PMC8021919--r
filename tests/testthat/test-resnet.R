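test_that("the built network has 12 blocks and 26 main-path layers", {
  spec <- resnet_spec(3, stem_width = 4)
  m <- resnet_build(spec, seed = 1)
  expect_identical(spec$n_blocks, 12L)
  expect_identical(n_weighted_layers(m), 26L)
  # two 3x3x3 convolutions per block
  for (b in 1:12) {
    blk <- m$params[[paste0("block", b)]]
    expect_identical(nrow(blk$conv1) %% 27L, 0L)
    expect_identical(nrow(blk$conv2) %% 27L, 0L)
  }
  # three stride-2 blocks, widths doubling per stage
  expect_identical(spec$stride2_block_indices, c(4L, 7L, 10L))
  expect_identical(spec$stage_widths, c(4L, 8L, 16L, 32L))
})

test_that("the network maps (N, C, D, H, W) batches to N predictions", {
  spec <- resnet_spec(3, stem_width = 2)
  m <- resnet_build(spec, seed = 1, input_dims = c(24, 24, 24))
  set.seed(4)
  x <- array(rnorm(24^3 * 3 * 4), dim = c(24, 24, 24, 3, 4))
  p <- predict(m, x)
  expect_identical(length(p), 4L)
  expect_true(all(is.finite(p)))
  # evaluation mode is deterministic
  expect_identical(p, predict(m, x))
})

test_that("builds are deterministic and grids must be divisible by 8", {
  spec <- resnet_spec(2, stem_width = 2)
  m1 <- resnet_build(spec, seed = 7)
  m2 <- resnet_build(spec, seed = 7)
  expect_identical(m1$params, m2$params)
  expect_identical(n_parameters(m1), n_parameters(m2))
  expect_error(resnet_build(spec, seed = 1, input_dims = c(20, 20, 20)),
               "divisible")
})

test_that("sex input adds one pooled feature before the linear layer", {
  base <- resnet_build(resnet_spec(2, stem_width = 2), seed = 1)
  with_sex <- resnet_build(resnet_spec(2, stem_width = 2, sex_input = TRUE),
                           seed = 1)
  expect_identical(n_parameters(with_sex), n_parameters(base) + 1L)
  x <- array(rnorm(8^3 * 2 * 2), dim = c(8, 8, 8, 2, 2))
  expect_error(brainagekit:::.resnet_fwd(with_sex, x), "sex")
  p <- brainagekit:::.resnet_fwd(with_sex, x, sex = c(0, 1))$pred
  expect_identical(length(p), 2L)
})

test_that("the LR schedule drops tenfold at 50% and 75% of training", {
  expect_equal(lr_schedule(0.1, 4), c(0.1, 0.1, 0.01, 0.001))
  s300 <- lr_schedule(0.1, 300)
  expect_equal(unique(s300[1:150]), 0.1)
  expect_equal(unique(s300[151:225]), 0.01)
  expect_equal(unique(s300[226:300]), 0.001)
})

test_that("training records one checkpoint per epoch and is reproducible", {
  cfg <- phantom_config(n_subjects = 16, grid = c(8, 8, 8), n_parcels = 4,
                        channels = c("t1", "gmv", "wmv"), seed = 44)
  co <- make_cohort(cfg)
  ages <- co$records$age
  x <- brainagekit:::stack_cohort(co$volumes, c("t1", "gmv", "wmv"))
  m <- resnet_build(resnet_spec(3, stem_width = 2), seed = 2)
  tc <- train_config(epochs = 3, batch_size = 4, seed = 5)
  f1 <- train_resnet(m, x[, , , , 1:12, drop = FALSE], ages[1:12],
                     x[, , , , 13:16, drop = FALSE], ages[13:16], tc)
  expect_identical(nrow(f1$records), 3L)
  expect_identical(f1$records$lr, lr_schedule(0.1, 3))
  expect_true(any(f1$records$best))
  expect_identical(f1$best_epoch,
                   f1$records$epoch[which.min(f1$records$val_mae)])
  f2 <- train_resnet(m, x[, , , , 1:12, drop = FALSE], ages[1:12],
                     x[, , , , 13:16, drop = FALSE], ages[13:16], tc)
  expect_identical(f1$records, f2$records)
})

test_that("covariance regularization reduces age-covarying error on a frozen readout", {
  # one linear readout neuron on a fixed feature; SGD on (w, b) with the
  # composite loss, full-batch
  set.seed(21)
  y <- runif(64, 17, 90)
  feat <- 0.5 * y + rnorm(64, 0, 4)       # feature with age-dependent scale
  run <- function(mode) {
    w <- 0; b <- 0
    for (it in 1:20000) {
      yp <- w * feat + b
      g <- brainagekit:::composite_loss_grad(prediction_batch(y, yp), mode,
                                             reg_weight = 1e-6)
      w <- w - 1e-5 * sum(g * feat)
      b <- b - 1e-2 * sum(g)
    }
    yp <- w * feat + b
    abs(cov(yp - y, y))
  }
  expect_lt(run("cov_reg"), run("plain"))
})
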