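# Independent per-layer arithmetic for the trainable-parameter count.
expected_param_count <- function(cfg) {
  k <- cfg$kernel
  conv <- function(cin, cout, kk = k) kk * kk * cin * cout + cout
  bn <- function(c) 2 * c
  total <- conv(3, cfg$stem_width) + bn(cfg$stem_width)
  cin <- cfg$stem_width
  for (cout in cfg$block_widths) {
    total <- total + conv(cin, cout) + 3 * conv(cout, cout) + 4 * bn(cout) +
      conv(cin, cout, kk = 1)  # 1x1 projection shortcut
    cin <- cout
  }
  total + cin * cfg$n_classes + cfg$n_classes
}

test_that("the architecture has the stated shapes", {
  cfg <- cnn_config(512)
  expect_identical(cfg$prepool_side, 32L)        # 512 / 2^4
  expect_identical(cfg$embedding_dim, 256L)
  expect_error(cnn_config(100), "16")
  net <- build_model(tiny_cnn(), seed = 2)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  fw <- forward_cnn(net, x)
  expect_identical(dim(fw$probs), c(2L, 2L))
  expect_identical(dim(fw$emb), c(2L, 8L))
  expect_equal(rowSums(fw$probs), c(1, 1), tolerance = 1e-6)
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
  expect_error(forward_cnn(net, array(0, c(16, 16, 3, 1))), "32 x 32")
})

test_that("parameter counts match independent per-layer arithmetic", {
  for (cfg in list(tiny_cnn(), cnn_config_desk(), cnn_config(512))) {
    net <- build_model(cfg, seed = 1)
    expect_identical(count_parameters(net), as.integer(expected_param_count(cfg)))
  }
  # worked examples: a 3x3 conv 3->16 with bias has 448 parameters, the
  # 256-d linear head 514
  full <- build_model(cnn_config(512, stem_width = 16), seed = 1)
  expect_identical(length(full$params[["stem.conv.w"]]) +
                     length(full$params[["stem.conv.b"]]), 448L)
  expect_identical(length(full$params[["head.w"]]) +
                     length(full$params[["head.b"]]), 514L)
})

test_that("eval-mode inference is deterministic and per-sample independent", {
  net <- build_model(tiny_cnn(), seed = 3)
  set.seed(10)
  x <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  a <- forward_cnn(net, x)
  b <- forward_cnn(net, x)
  expect_identical(a$probs, b$probs)
  perm <- c(3, 1, 4, 2)
  p <- forward_cnn(net, x[, , , perm, drop = FALSE])
  expect_equal(p$probs, a$probs[perm, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zeroing the post-downsample convolutions reduces each block to its projected shortcut", {
  net <- build_model(tiny_cnn(), seed = 4)
  for (i in 1:4) for (j in 2:4) {
    net$params[[sprintf("b%d.conv%d.w", i, j)]][] <- 0
    net$params[[sprintf("b%d.conv%d.b", i, j)]][] <- 0
  }
  set.seed(11)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  fw <- forward_cnn(net, x, training = FALSE)
  # independent reconstruction: stem unit, then only the projection chain
  P <- net$params
  bn_eval <- function(a, nm) {
    d <- dim(a); HW <- d[1] * d[2]
    g <- P[[paste0(nm, ".g")]]; b <- P[[paste0(nm, ".b")]]
    mu <- net$bn[[paste0(nm, ".mean")]]; v <- net$bn[[paste0(nm, ".var")]]
    y <- a * rep(g / sqrt(v + 1e-5), each = HW) +
      rep(b - mu * g / sqrt(v + 1e-5), each = HW)
    dim(y) <- d; y
  }
  h <- bn_eval(pmax(hescreen:::conv_fwd(x, P[["stem.conv.w"]], P[["stem.conv.b"]], 1L), 0),
               "stem.bn")
  for (i in 1:4)
    h <- hescreen:::conv_fwd(h, P[[sprintf("b%d.proj.w", i)]],
                             P[[sprintf("b%d.proj.b", i)]], 2L)
  emb <- t(apply(h, 3:4, mean))
  expect_equal(fw$emb, emb, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("analytic gradients match finite differences", {
  cfg <- cnn_config(input_side = 16, stem_width = 2, block_widths = c(2, 2, 3, 3))
  net <- build_model(cfg, seed = 7)
  set.seed(42)
  x <- array(runif(16 * 16 * 3 * 3), c(16, 16, 3, 3))
  y <- c(0L, 1L, 1L)
  loss_at <- function(net) {
    fw <- forward_cnn(net, x, training = TRUE)
    focal_loss(fw$probs, y, gamma = 3)
  }
  fw <- forward_cnn(net, x, training = TRUE)
  dz <- hescreen:::focal_grad_logits(fw$probs, y, gamma = 3)
  G <- hescreen:::backward_cnn(net, fw, dz)
  expect_setequal(names(G), names(net$params))
  eps <- 1e-6
  set.seed(1)
  for (nm in c("stem.conv.w", "b1.conv1.w", "b2.conv3.w", "b3.bn2.g",
               "b4.proj.w", "b2.bn4.b", "head.w", "head.b")) {
    for (i in sample(length(net$params[[nm]]), min(3, length(net$params[[nm]])))) {
      n2 <- net
      n2$params[[nm]][i] <- net$params[[nm]][i] + eps
      lp <- loss_at(n2)
      n2$params[[nm]][i] <- net$params[[nm]][i] - eps
      lm <- loss_at(n2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(G[[nm]][i], num, tolerance = 1e-3,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("gradients flow to every trainable parameter", {
  net <- build_model(tiny_cnn(), seed = 5)
  set.seed(12)
  x <- array(runif(32 * 32 * 3 * 8), c(32, 32, 3, 8))
  y <- rep(0:1, 4)
  fw <- forward_cnn(net, x, training = TRUE)
  dz <- hescreen:::focal_grad_logits(fw$probs, y, gamma = 3)
  G <- hescreen:::backward_cnn(net, fw, dz)
  for (nm in names(net$params)) {
    expect_true(all(is.finite(G[[nm]])), label = paste("finite grad", nm))
    expect_gt(sum(abs(G[[nm]])), 0, label = paste("live grad", nm))
  }
})

test_that("focal loss reduces to cross-entropy at gamma 0 and evaluates in closed form", {
  set.seed(13)
  p_pos <- runif(40, 0.01, 0.99)
  probs <- cbind(1 - p_pos, p_pos)
  labels <- rbinom(40, 1, 0.5)
  ce <- mean(-log(ifelse(labels == 1, p_pos, 1 - p_pos)))
  expect_equal(focal_loss(probs, labels, gamma = 0), ce, tolerance = 1e-9)
  # worked example: single sample, p_t = 0.5, gamma = 3 -> 0.125 * ln 2
  expect_equal(focal_loss(matrix(c(0.5, 0.5), 1), 1L, gamma = 3),
               0.125 * log(2), tolerance = 1e-12)
  # zero iff perfectly confident
  expect_equal(focal_loss(cbind(0, 1), 1L, gamma = 3), 0, tolerance = 1e-6)
  expect_gt(focal_loss(cbind(0.3, 0.7), 1L, gamma = 3), 0)
  expect_error(focal_loss(probs, labels, gamma = -1), "gamma")
})

test_that("the focal gradient is finite at the probability extremes", {
  probs <- rbind(c(1e-12, 1 - 1e-12), c(1 - 1e-12, 1e-12))
  g <- hescreen:::focal_grad_logits(probs, c(1L, 1L), gamma = 3)
  expect_true(all(is.finite(g)))
  g0 <- hescreen:::focal_grad_logits(probs, c(1L, 0L), gamma = 0)
  expect_true(all(is.finite(g0)))
})
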