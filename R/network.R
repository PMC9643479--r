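# Residual CNN: stem (conv -> ReLU -> BatchNorm) + 4 downsampling residual
# blocks + global average pooling + 2-way linear head.
#
# Each block is a stride-2 3x3 convolution followed by three stride-1 3x3
# convolutions, every convolution followed by ReLU then BatchNorm (this
# conv -> ReLU -> BN order is a deliberate architectural choice), with a
# 1x1 stride-2 projection shortcut added to the block output.  Forward and
# backward passes are written out explicitly; convolutions run through the
# compiled im2col/GEMM kernels, everything else is vectorised base R.
#
# Tensors are (height, width, channels, batch) arrays.

#' CNN architecture configuration
#'
#' Four residual blocks each halve the spatial dimensions, so the pre-pool
#' feature map is `input_side / 16` on a side and the embedding dimension is
#' the last block width (256 at full scale).
#'
#' @param input_side input resolution in pixels; must be divisible by 16.
#' @param stem_width channels of the initial convolution.
#' @param block_widths channel counts of the 4 residual blocks; the last is
#'   the embedding dimension.
#' @param n_classes output classes (2).
#' @param kernel convolution kernel side (3).
#' @return a `cnn_config` object.
#' @export
cnn_config <- function(input_side = 512, stem_width = 16,
                       block_widths = c(32, 64, 128, 256),
                       n_classes = 2, kernel = 3) {
  if (!is_count(input_side) || input_side %% 16 != 0 || input_side < 16)
    stopf("input_side must be a positive multiple of 16 (4 blocks each halve it)")
  if (length(block_widths) != 4 || any(block_widths < 1))
    stopf("block_widths must give 4 positive channel counts")
  structure(list(input_side = as.integer(input_side),
                 stem_width = as.integer(stem_width),
                 block_widths = as.integer(block_widths),
                 embedding_dim = as.integer(block_widths[4]),
                 n_classes = as.integer(n_classes),
                 kernel = as.integer(kernel),
                 prepool_side = as.integer(input_side / 16)),
            class = "cnn_config")
}

#' Desk-scale CNN configuration
#'
#' A width-8 stem at 64 px input, used throughout the test suite; same
#' topology as the full-scale model.
#'
#' @param input_side input resolution (default 64).
#' @return a `cnn_config`.
#' @export
cnn_config_desk <- function(input_side = 64) {
  cnn_config(input_side = input_side, stem_width = 8, block_widths = c(8, 16, 32, 64))
}

init_conv <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))), c(k, k, cin, cout))
}

#' Build an untrained network
#'
#' He-initialised weights, zero biases, unit BatchNorm scale with zero
#' running means and unit running variances.
#'
#' @param config a [cnn_config()].
#' @param seed RNG seed for the weight initialisation.
#' @return an object of class `hecnn_net` holding `params` (trainable
#'   arrays), `bn` (BatchNorm running statistics, not trainable), and the
#'   config.
#' @export
build_model <- function(config = cnn_config(), seed = 1) {
  stopifnot(inherits(config, "cnn_config"))
  with_seed(seed, {
    k <- config$kernel
    P <- list()
    B <- list()
    add_bn <- function(name, c) {
      P[[paste0(name, ".g")]] <<- rep(1, c)
      P[[paste0(name, ".b")]] <<- rep(0, c)
      B[[paste0(name, ".mean")]] <<- rep(0, c)
      B[[paste0(name, ".var")]] <<- rep(1, c)
    }
    P[["stem.conv.w"]] <- init_conv(k, 3, config$stem_width)
    P[["stem.conv.b"]] <- rep(0, config$stem_width)
    add_bn("stem.bn", config$stem_width)
    cin <- config$stem_width
    for (i in 1:4) {
      cout <- config$block_widths[i]
      for (j in 1:4) {
        cj <- if (j == 1) cin else cout
        P[[sprintf("b%d.conv%d.w", i, j)]] <- init_conv(k, cj, cout)
        P[[sprintf("b%d.conv%d.b", i, j)]] <- rep(0, cout)
        add_bn(sprintf("b%d.bn%d", i, j), cout)
      }
      P[[sprintf("b%d.proj.w", i)]] <- init_conv(1, cin, cout)
      P[[sprintf("b%d.proj.b", i)]] <- rep(0, cout)
      cin <- cout
    }
    P[["head.w"]] <- matrix(rnorm(cin * config$n_classes, 0, sqrt(1 / cin)),
                            cin, config$n_classes)
    P[["head.b"]] <- rep(0, config$n_classes)
    structure(list(config = config, params = P, bn = B, version = "hecnn-1"),
              class = "hecnn_net")
  })
}

#' Count trainable parameters
#'
#' Sum of element counts over all trainable arrays (convolution and linear
#' weights/biases, BatchNorm scale/shift); BatchNorm running statistics are
#' excluded.
#'
#' @param net an `hecnn_net` (or a fitted `hecnn` model).
#' @return integer parameter count.
#' @export
count_parameters <- function(net) {
  if (inherits(net, "hecnn")) net <- net$net
  sum(vapply(net$params, length, 0L))
}

conv_fwd <- function(x, w, b, stride) {
  k <- dim(w)[1]
  conv2d_forward_cpp(x, dim(x), w, dim(w), b,
                     as.integer(stride), as.integer((k - 1) %/% 2))
}

conv_bwd <- function(x, w, dy, stride) {
  k <- dim(w)[1]
  conv2d_backward_cpp(x, dim(x), w, dim(w), dy,
                      as.integer(stride), as.integer((k - 1) %/% 2))
}

bn_channel_stats <- function(x) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(x, HW, C * N)
  cm <- colMeans(xm); cm2 <- colMeans(xm * xm)
  mu <- rowMeans(matrix(cm, C, N))
  ex2 <- rowMeans(matrix(cm2, C, N))
  list(mean = mu, var = pmax(ex2 - mu^2, 0))
}

bn_fwd <- function(x, g, b, rmean, rvar, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]
  if (training) {
    st <- bn_channel_stats(x); mu <- st$mean; v <- st$var
  } else {
    mu <- rmean; v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  y <- x * rep(g * invstd, each = HW) + rep(b - mu * g * invstd, each = HW)
  dim(y) <- d
  list(y = y, mu = mu, invstd = invstd,
       new_mean = if (training) (1 - momentum) * rmean + momentum * mu else rmean,
       new_var = if (training) (1 - momentum) * rvar + momentum * v else rvar)
}

# Backward through a train-mode BatchNorm (batch statistics are functions of
# the input; the standard three-term gradient accounts for that).
bn_bwd <- function(dy, x, g, mu, invstd) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]; M <- HW * N
  xhat <- (x - rep(mu, each = HW)) * rep(invstd, each = HW)
  csum <- function(a) {
    m <- matrix(a, HW, C * N)
    rowSums(matrix(colSums(m), C, N))
  }
  s1 <- csum(dy); s2 <- csum(dy * xhat)
  dx <- rep(g * invstd / M, each = HW) * (M * dy - rep(s1, each = HW) - xhat * rep(s2, each = HW))
  dim(dx) <- d
  list(dx = dx, dg = s2, db = s1)
}

gap_fwd <- function(x) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  t(matrix(colMeans(matrix(x, HW, C * N)), C, N))  # N x C
}

gap_bwd <- function(demb, d) {
  HW <- d[1] * d[2]
  dx <- rep(as.vector(t(demb)) / HW, each = HW)
  dim(dx) <- d
  dx
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass
#'
#' @param net an `hecnn_net`.
#' @param x input batch, array `(side, side, 3, n)`.
#' @param training if `TRUE`, BatchNorm uses batch statistics and a cache for
#'   the backward pass is kept; in eval mode the pass is deterministic
#'   (fixed running statistics).
#' @return list with `probs` (n x 2, rows sum to 1), `logits`, `emb`
#'   (n x embedding_dim), `newbn` (updated running statistics when
#'   training), and `cache` (training only).
#' @export
forward_cnn <- function(net, x, training = FALSE) {
  cfg <- net$config; P <- net$params; B <- net$bn
  d <- dim(x)
  if (length(d) != 4 || d[1] != cfg$input_side || d[2] != cfg$input_side || d[3] != 3)
    stopf("input batch must be %d x %d x 3 x n, got %s",
          cfg$input_side, cfg$input_side, paste(d, collapse = "x"))
  newbn <- B
  keep <- isTRUE(training)
  run_unit <- function(xin, base, bnname, stride) {
    z <- conv_fwd(xin, P[[paste0(base, ".w")]], P[[paste0(base, ".b")]], stride)
    a <- pmax(z, 0)
    bn <- bn_fwd(a, P[[paste0(bnname, ".g")]], P[[paste0(bnname, ".b")]],
                 B[[paste0(bnname, ".mean")]], B[[paste0(bnname, ".var")]], training)
    if (training) {
      newbn[[paste0(bnname, ".mean")]] <<- bn$new_mean
      newbn[[paste0(bnname, ".var")]] <<- bn$new_var
    }
    list(y = bn$y,
         cache = if (keep) list(x = xin, z = z, a = a, mu = bn$mu, invstd = bn$invstd))
  }
  stem <- run_unit(x, "stem.conv", "stem.bn", 1L)
  h <- stem$y
  blocks <- vector("list", 4)
  for (i in 1:4) {
    inp <- h
    units <- vector("list", 4)
    cur <- inp
    for (j in 1:4) {
      u <- run_unit(cur, sprintf("b%d.conv%d", i, j), sprintf("b%d.bn%d", i, j),
                    if (j == 1) 2L else 1L)
      units[[j]] <- u$cache
      cur <- u$y
    }
    short <- conv_fwd(inp, P[[sprintf("b%d.proj.w", i)]],
                      P[[sprintf("b%d.proj.b", i)]], 2L)
    h <- cur + short
    if (keep) blocks[[i]] <- list(input = inp, units = units)
  }
  emb <- gap_fwd(h)
  logits <- emb %*% P[["head.w"]] + rep(P[["head.b"]], each = nrow(emb))
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, emb = emb, newbn = newbn,
       cache = if (keep) list(stem = stem$cache, blocks = blocks,
                              h_dim = dim(h), emb = emb))
}

# Backward pass: gradient of the scalar loss w.r.t. every trainable
# parameter, given d(loss)/d(logits).
backward_cnn <- function(net, fw, dlogits) {
  P <- net$params; cache <- fw$cache
  if (is.null(cache)) stopf("backward requires a training-mode forward pass")
  G <- list()
  G[["head.w"]] <- t(cache$emb) %*% dlogits
  G[["head.b"]] <- colSums(dlogits)
  demb <- dlogits %*% t(P[["head.w"]])
  dh <- gap_bwd(demb, cache$h_dim)
  unit_bwd <- function(dcur, uc, base, bnname, stride) {
    bb <- bn_bwd(dcur, uc$a, P[[paste0(bnname, ".g")]], uc$mu, uc$invstd)
    G[[paste0(bnname, ".g")]] <<- bb$dg
    G[[paste0(bnname, ".b")]] <<- bb$db
    dz <- bb$dx * (uc$z > 0)
    cb <- conv_bwd(uc$x, P[[paste0(base, ".w")]], dz, stride)
    G[[paste0(base, ".w")]] <<- cb$dw
    G[[paste0(base, ".b")]] <<- cb$db
    cb$dx
  }
  for (i in 4:1) {
    blk <- cache$blocks[[i]]
    pb <- conv_bwd(blk$input, P[[sprintf("b%d.proj.w", i)]], dh, 2L)
    G[[sprintf("b%d.proj.w", i)]] <- pb$dw
    G[[sprintf("b%d.proj.b", i)]] <- pb$db
    dcur <- dh
    for (j in 4:1) {
      dcur <- unit_bwd(dcur, blk$units[[j]], sprintf("b%d.conv%d", i, j),
                       sprintf("b%d.bn%d", i, j), if (j == 1) 2L else 1L)
    }
    dh <- dcur + pb$dx
  }
  unit_bwd(dh, cache$stem, "stem.conv", "stem.bn", 1L)
  G
}

#' Focal loss
#'
#' `FL(p_t) = -(1 - p_t)^gamma * log(p_t)`, averaged over the batch, where
#' `p_t` is the predicted probability of the true class.  `gamma = 0` reduces
#' exactly to mean cross-entropy; larger gamma down-weights well-classified
#' examples, which is how class imbalance is handled (no alpha weighting, no
#' oversampling).
#'
#' @param probs n x 2 matrix of class probabilities (rows sum to 1), or a
#'   vector of true-class probabilities `p_t`.
#' @param labels integer 0/1 vector (ignored when `probs` is a `p_t` vector).
#' @param gamma focusing exponent, >= 0 (3 in the shipped training
#'   configuration).
#' @param eps numerical floor applied to `p_t` before the logarithm.
#' @return scalar mean loss (nats); non-negative, zero iff all `p_t = 1`.
#' @export
focal_loss <- function(probs, labels = NULL, gamma = 3, eps = 1e-7) {
  if (gamma < 0) stopf("gamma must be >= 0")
  p <- if (is.matrix(probs)) {
    if (is.null(labels) || length(labels) != nrow(probs))
      stopf("labels must align with the probability rows")
    probs[cbind(seq_len(nrow(probs)), as.integer(labels) + 1L)]
  } else as.numeric(probs)
  p <- pmax(pmin(p, 1), eps)
  mean(-(1 - p)^gamma * log(p))
}

# d(mean focal loss)/d(logits); reduces to (q - onehot)/n at gamma = 0.
focal_grad_logits <- function(probs, labels, gamma = 3, eps = 1e-7) {
  n <- nrow(probs)
  t1 <- as.integer(labels) + 1L
  p <- pmax(probs[cbind(seq_len(n), t1)], eps)
  pm1 <- pmax(1 - p, eps)
  coef <- gamma * p * pm1^(gamma - 1) * log(p) - pm1^gamma
  delta <- matrix(0, n, ncol(probs))
  delta[cbind(seq_len(n), t1)] <- 1
  coef * (delta - probs) / n
}
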