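# The 26-layer 3D residual age regressor.
#
# Architecture: one stem 3x3x3 convolution, 12 residual blocks (each block:
# conv-BN-ReLU-dropout-conv-BN, shortcut add, ReLU; two 3x3x3 convolutions
# per block), global average pooling and a single linear output unit.
# Main-path weighted layers: 1 stem conv + 24 block convs + 1 linear = 26.
# Three blocks use stride 2 in their first convolution, halving each
# spatial axis, with a 1x1x1 stride-2 convolution (plus BN) on the
# shortcut. Channel widths double at each stride-2 stage. With `sex_input`,
# a 0/1 scalar is concatenated to the pooled feature vector before the
# linear layer.
#
# Forward and backward passes are written against the package's own conv3d
# kernels (vol2col + GEMM); batch norm, ReLU, inverted dropout, pooling and
# the linear head are plain R array arithmetic. Arrays are laid out
# (x, y, z, channel, subject).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Specification of the 26-layer 3D residual regressor
#'
#' @param in_channels number of input channels.
#' @param stem_width stem output width; stage widths default to
#'   `stem_width * c(1, 2, 4, 8)` (doubling at each stride-2 stage).
#' @param stage_widths optional explicit widths for the 4 stages.
#' @param dropout_rate dropout probability inside each block.
#' @param sex_input concatenate a 0/1 sex scalar to the pooled features.
#' @return object of class `resnet_spec` (12 blocks; stride-2 blocks are
#'   the first block of stages 2-4, i.e. blocks 4, 7, 10).
#' @export
resnet_spec <- function(in_channels, stem_width = 16L, stage_widths = NULL,
                        dropout_rate = 0.1, sex_input = FALSE) {
  stage_widths <- as.integer(stage_widths %||% (stem_width * c(1, 2, 4, 8)))
  if (length(stage_widths) != 4) stopf("need 4 stage widths")
  structure(list(in_channels = as.integer(in_channels),
                 stem_width = as.integer(stem_width),
                 stage_widths = stage_widths,
                 n_blocks = 12L,
                 stride2_block_indices = c(4L, 7L, 10L),
                 dropout_rate = dropout_rate,
                 sex_input = isTRUE(sex_input)),
            class = "resnet_spec")
}

# Per-block (in-width, out-width, stride) table derived from the spec.
.block_plan <- function(spec) {
  stage_of <- rep(1:4, each = 3)
  plan <- data.frame(block = 1:12,
                     stage = stage_of,
                     cout = spec$stage_widths[stage_of])
  plan$cin <- c(spec$stem_width, plan$cout[-12])
  plan$stride <- ifelse(plan$block %in% spec$stride2_block_indices, 2L, 1L)
  plan
}

.conv_init <- function(k, cin, cout) {
  # He (fan-in) initialization
  matrix(rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
         nrow = k^3 * cin, ncol = cout)
}

.bn_init <- function(c) list(gamma = rep(1, c), beta = rep(0, c),
                             rmean = rep(0, c), rvar = rep(1, c))

#' Build a 26-layer 3D residual regressor
#'
#' Initializes all weights (He initialization for convolutions, BN gamma=1 /
#' beta=0, small-normal linear head) deterministically from `seed`.
#'
#' @param spec a [resnet_spec()].
#' @param seed integer seed.
#' @param input_dims optional grid dims; if given, each axis must be
#'   divisible by 2^3 (three stride-2 stages) or the build fails.
#' @return object of class `resnet26`.
#' @export
resnet_build <- function(spec, seed = 1L, input_dims = NULL) {
  if (!is.null(input_dims)) .check_grid(input_dims)
  plan <- .block_plan(spec)
  params <- with_seed(hash_seed(seed, "resnet-init"), {
    p <- list(stem_w = .conv_init(3, spec$in_channels, spec$stem_width),
              stem_bn = .bn_init(spec$stem_width))
    for (b in 1:12) {
      pb <- list(conv1 = .conv_init(3, plan$cin[b], plan$cout[b]),
                 bn1 = .bn_init(plan$cout[b]),
                 conv2 = .conv_init(3, plan$cout[b], plan$cout[b]),
                 bn2 = .bn_init(plan$cout[b]))
      if (plan$stride[b] == 2 || plan$cin[b] != plan$cout[b]) {
        pb$proj <- .conv_init(1, plan$cin[b], plan$cout[b])
        pb$bnp <- .bn_init(plan$cout[b])
      }
      p[[paste0("block", b)]] <- pb
    }
    nfeat <- spec$stage_widths[4] + spec$sex_input
    p$fc_w <- matrix(rnorm(nfeat, 0, 1 / sqrt(nfeat)), nrow = nfeat)
    p$fc_b <- 0
    p
  })
  structure(list(spec = spec, plan = plan, params = params, seed = seed),
            class = "resnet26")
}

.check_grid <- function(dims) {
  if (any(dims %% 8 != 0))
    stopf("input grid %s not divisible by 8 (three stride-2 stages)",
          paste(dims, collapse = "x"))
  if (any(dims / 8 < 1)) stopf("grid too small after three halvings")
  invisible(dims)
}

#' Count the main-path weighted layers of a built model
#'
#' Stem convolution + two convolutions per residual block + the final
#' linear layer (shortcut projections sit off the main path).
#'
#' @param model a `resnet26`.
#' @return integer layer count.
#' @export
n_weighted_layers <- function(model) {
  1L + 2L * model$spec$n_blocks + 1L
}

#' Count parameters of a built model
#' @param model a `resnet26`.
#' @return total number of scalar parameters.
#' @export
n_parameters <- function(model) {
  cnt <- 0
  walk <- function(x) for (v in x)
    if (is.list(v)) walk(v) else cnt <<- cnt + length(v)
  walk(model$params)
  cnt
}

#' @export
print.resnet26 <- function(x, ...) {
  cat(sprintf("26-layer 3D residual regressor: %d input channel(s), widths %s\n",
              x$spec$in_channels, paste(x$spec$stage_widths, collapse = "/")))
  cat(sprintf("  12 blocks (stride 2 at %s), dropout %.2f, sex input: %s, %d parameters\n",
              paste(x$spec$stride2_block_indices, collapse = ","),
              x$spec$dropout_rate, x$spec$sex_input, n_parameters(x)))
  invisible(x)
}

# --- primitive layers ------------------------------------------------------

.bn_fwd <- function(x, bn, training) {
  d <- dim(x); C <- d[4]
  xp <- aperm(x, c(1, 2, 3, 5, 4))
  dim(xp) <- c(prod(d[-4]), C)
  if (training) {
    mu <- colMeans(xp)
    v <- colMeans(xp^2) - mu^2
    bn$rmean <- (1 - BN_MOMENTUM) * bn$rmean + BN_MOMENTUM * mu
    m <- nrow(xp)
    bn$rvar <- (1 - BN_MOMENTUM) * bn$rvar +
      BN_MOMENTUM * v * m / max(m - 1, 1)
  } else {
    mu <- bn$rmean; v <- bn$rvar
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(xp, 2, mu) * rep(invstd, each = nrow(xp))
  yp <- xhat * rep(bn$gamma, each = nrow(xp)) +
    rep(bn$beta, each = nrow(xp))
  dim(yp) <- c(d[1], d[2], d[3], d[5], C)
  y <- aperm(yp, c(1, 2, 3, 5, 4))
  list(y = y, bn = bn,
       cache = list(xhat = xhat, invstd = invstd, gamma = bn$gamma, d = d))
}

.bn_bwd <- function(dy, cache) {
  d <- cache$d; C <- d[4]
  dyp <- aperm(dy, c(1, 2, 3, 5, 4))
  dim(dyp) <- c(prod(d[-4]), C)
  m <- nrow(dyp)
  dgamma <- colSums(dyp * cache$xhat)
  dbeta <- colSums(dyp)
  dxhat <- dyp * rep(cache$gamma, each = m)
  t1 <- colSums(dxhat)
  t2 <- colSums(dxhat * cache$xhat)
  dxp <- (dxhat - rep(t1 / m, each = m) -
            cache$xhat * rep(t2 / m, each = m)) *
    rep(cache$invstd, each = m)
  dim(dxp) <- c(d[1], d[2], d[3], d[5], C)
  list(dx = aperm(dxp, c(1, 2, 3, 5, 4)), dgamma = dgamma, dbeta = dbeta)
}

.dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim = dim(x))
  list(y = x * mask, mask = mask)
}

# --- full network forward/backward -----------------------------------------

# Forward pass. Returns predictions, the updated model (BN running stats)
# and, when keep_cache, everything needed for the backward pass.
.resnet_fwd <- function(model, x, sex = NULL, training = FALSE,
                        keep_cache = FALSE) {
  spec <- model$spec; p <- model$params
  if (spec$sex_input && is.null(sex)) stopf("spec requires sex input")
  cache <- list()
  h <- .conv3d_fwd(x, p$stem_w, 3L, 1L, 1L)
  if (keep_cache) cache$stem_x <- x
  bnr <- .bn_fwd(h, p$stem_bn, training)
  p$stem_bn <- bnr$bn
  if (keep_cache) { cache$stem_bn <- bnr$cache; cache$stem_pre <- h }
  h <- bnr$y
  pos <- h > 0
  h <- h * pos
  if (keep_cache) cache$stem_pos <- pos
  for (b in 1:12) {
    key <- paste0("block", b)
    pb <- p[[key]]
    stride <- model$plan$stride[b]
    cb <- list(x = if (keep_cache) h else NULL, stride = stride)
    h1 <- .conv3d_fwd(h, pb$conv1, 3L, stride, 1L)
    bn1 <- .bn_fwd(h1, pb$bn1, training); pb$bn1 <- bn1$bn
    pos1 <- bn1$y > 0
    r1 <- bn1$y * pos1
    dr <- .dropout_fwd(r1, spec$dropout_rate, training)
    h2 <- .conv3d_fwd(dr$y, pb$conv2, 3L, 1L, 1L)
    bn2 <- .bn_fwd(h2, pb$bn2, training); pb$bn2 <- bn2$bn
    if (!is.null(pb$proj)) {
      s <- .conv3d_fwd(h, pb$proj, 1L, stride, 0L)
      bnp <- .bn_fwd(s, pb$bnp, training); pb$bnp <- bnp$bn
      sc <- bnp$y
    } else {
      sc <- h; bnp <- NULL
    }
    out <- bn2$y + sc
    pos_out <- out > 0
    h <- out * pos_out
    if (keep_cache) {
      cb$bn1 <- bn1$cache; cb$pos1 <- pos1; cb$drop_mask <- dr$mask
      cb$drop_in <- dr$y; cb$bn2 <- bn2$cache
      cb$bnp <- if (is.null(bnp)) NULL else bnp$cache
      cb$pos_out <- pos_out
      cache[[key]] <- cb
    }
    p[[key]] <- pb
  }
  d <- dim(h)
  S <- prod(d[1:3])
  hm <- h; dim(hm) <- c(S, d[4] * d[5])
  feat <- matrix(colMeans(hm), nrow = d[4])      # C x N pooled features
  if (keep_cache) { cache$pool_dim <- d; cache$feat <- feat }
  f <- if (spec$sex_input) rbind(feat, as.numeric(sex)) else feat
  if (keep_cache) cache$fc_in <- f
  pred <- as.numeric(crossprod(p$fc_w, f)) + p$fc_b
  model$params <- p
  list(pred = pred, model = model, cache = if (keep_cache) cache else NULL)
}

# Backward pass from d(loss)/d(pred); returns gradients for every
# parameter, in the same nested structure as model$params.
.resnet_bwd <- function(model, cache, dpred) {
  spec <- model$spec; p <- model$params
  g <- list()
  f <- cache$fc_in
  g$fc_w <- f %*% matrix(dpred, ncol = 1)
  g$fc_b <- sum(dpred)
  dfeat <- p$fc_w %*% matrix(dpred, nrow = 1)    # (F x N)
  if (spec$sex_input) dfeat <- dfeat[-nrow(dfeat), , drop = FALSE]
  d <- cache$pool_dim
  S <- prod(d[1:3])
  dh <- array(rep(as.numeric(dfeat), each = S) / S, dim = d)
  for (b in 12:1) {
    key <- paste0("block", b)
    pb <- p[[key]]; cb <- cache[[key]]
    dout <- dh * cb$pos_out
    # shortcut branch
    if (!is.null(pb$proj)) {
      bnpb <- .bn_bwd(dout, cb$bnp)
      g[[key]]$bnp <- list(gamma = bnpb$dgamma, beta = bnpb$dbeta)
      pj <- .conv3d_bwd(cb$x, pb$proj, bnpb$dx, 1L, cb$stride, 0L)
      g[[key]]$proj <- pj$dw
      dsc <- pj$dx
    } else {
      dsc <- dout
    }
    # main branch
    bn2b <- .bn_bwd(dout, cb$bn2)
    g[[key]]$bn2 <- list(gamma = bn2b$dgamma, beta = bn2b$dbeta)
    c2 <- .conv3d_bwd(cb$drop_in, pb$conv2, bn2b$dx, 3L, 1L, 1L)
    g[[key]]$conv2 <- c2$dw
    dr1 <- if (is.null(cb$drop_mask)) c2$dx else c2$dx * cb$drop_mask
    dbn1 <- dr1 * cb$pos1
    bn1b <- .bn_bwd(dbn1, cb$bn1)
    g[[key]]$bn1 <- list(gamma = bn1b$dgamma, beta = bn1b$dbeta)
    c1 <- .conv3d_bwd(cb$x, pb$conv1, bn1b$dx, 3L, cb$stride, 1L)
    g[[key]]$conv1 <- c1$dw
    dh <- c1$dx + dsc
  }
  dh <- dh * cache$stem_pos
  bns <- .bn_bwd(dh, cache$stem_bn)
  g$stem_bn <- list(gamma = bns$dgamma, beta = bns$dbeta)
  cs <- .conv3d_bwd(cache$stem_x, p$stem_w, bns$dx, 3L, 1L, 1L)
  g$stem_w <- cs$dw
  g
}

#' Predict ages with a built (or trained) residual regressor
#'
#' Runs the network in evaluation mode (BN running statistics, no dropout).
#'
#' @param object a `resnet26`.
#' @param x input array `(x, y, z, channel, subject)`.
#' @param sex optional 0/1 vector (required when the spec has `sex_input`).
#' @param ... unused.
#' @return numeric vector of predicted ages.
#' @export
predict.resnet26 <- function(object, x, sex = NULL, ...) {
  .check_grid(dim(x)[1:3])
  if (dim(x)[4] != object$spec$in_channels)
    stopf("input has %d channels; spec expects %d",
          dim(x)[4], object$spec$in_channels)
  .resnet_fwd(object, x, sex = sex, training = FALSE)$pred
}
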