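test_that("convolution kernel matches a direct-loop oracle", {
  set.seed(1)
  x <- array(rnorm(6 * 5 * 3 * 2), c(6, 5, 3, 2))
  w <- array(rnorm(9 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  y <- nucseg:::cpp_conv3x3_fwd(x, w, b)
  expect_equal(y, naive_conv3x3(x, w, b), tolerance = 1e-5)
})

test_that("convolution backward matches analytic derivatives", {
  set.seed(2)
  H <- 5; W <- 4; Ci <- 2; Co <- 3
  x <- array(rnorm(H * W * Ci), c(H, W, Ci, 1))
  w <- array(rnorm(9 * Ci * Co), c(3, 3, Ci, Co))
  dy <- array(rnorm(H * W * Co), c(H, W, Co, 1))
  bw <- nucseg:::cpp_conv3x3_bwd(x, w, dy)
  # dX: correlation of dy with spatially flipped weights, channels swapped
  wf <- array(0, c(3, 3, Co, Ci))
  for (kh in 1:3) for (kw in 1:3) for (ci in 1:Ci) for (co in 1:Co)
    wf[4 - kh, 4 - kw, co, ci] <- w[kh, kw, ci, co]
  expect_equal(bw$dx, naive_conv3x3(dy, wf, numeric(Ci)), tolerance = 1e-5)
  # dW by direct summation of x-patches against dy
  dw_ref <- array(0, dim(w))
  for (kh in 1:3) for (kw in 1:3) for (ci in 1:Ci) for (co in 1:Co) {
    s <- 0
    for (h in 1:H) for (wd in 1:W) {
      hh <- h + kh - 2; ww <- wd + kw - 2
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
        s <- s + x[hh, ww, ci, 1] * dy[h, wd, co, 1]
    }
    dw_ref[kh, kw, ci, co] <- s
  }
  expect_equal(bw$dw, dw_ref, tolerance = 1e-5)
  expect_equal(bw$db, apply(dy, 3, sum), tolerance = 1e-5)
})

test_that("batch norm forward/backward match an R reference", {
  set.seed(3)
  x <- array(rnorm(4 * 3 * 2 * 2, mean = 1, sd = 2), c(4, 3, 2, 2))
  g <- c(1.5, 0.7); b <- c(0.2, -0.1); eps <- 1e-5
  fw <- nucseg:::cpp_bn_fwd(x, g, b, eps, TRUE, numeric(2), numeric(2))
  for (c in 1:2) {
    xc <- x[, , c, ]
    mu <- mean(xc); v <- mean((xc - mu)^2)
    expect_equal(fw$mean[c], mu, tolerance = 1e-12)
    expect_equal(fw$var[c], v, tolerance = 1e-12)
    expect_equal(fw$y[, , c, ], g[c] * (xc - mu) / sqrt(v + eps) + b[c],
                 tolerance = 1e-12)
  }
  # backward against central finite differences (all-double path)
  dy <- array(rnorm(length(x)), dim(x))
  bw <- nucseg:::cpp_bn_bwd(x, g, fw$mean, fw$var, dy, eps)
  lossf <- function(xp) {
    f <- nucseg:::cpp_bn_fwd(xp, g, b, eps, TRUE, numeric(2), numeric(2))
    sum(f$y * dy)
  }
  for (k in sample(length(x), 5)) {
    h <- 1e-6
    xp <- x; xp[k] <- x[k] + h; lp <- lossf(xp)
    xp[k] <- x[k] - h; lm <- lossf(xp)
    expect_equal(bw$dx[k], (lp - lm) / (2 * h), tolerance = 1e-4)
  }
  expect_equal(bw$dbeta, apply(dy, 3, sum), tolerance = 1e-10)
})

test_that("fused BN+ReLU equals BN followed by ReLU, with gated gradient", {
  set.seed(4)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  g <- runif(3, 0.5, 1.5); b <- rnorm(3); eps <- 1e-5
  plain <- nucseg:::cpp_bn_fwd(x, g, b, eps, TRUE, numeric(3), numeric(3))
  fused <- nucseg:::cpp_bn_fwd(x, g, b, eps, TRUE, numeric(3), numeric(3),
                               relu = TRUE)
  expect_equal(fused$y, pmax(plain$y, 0), tolerance = 1e-12)
  dy <- array(rnorm(length(x)), dim(x))
  gated <- dy * (plain$y > 0)
  ref <- nucseg:::cpp_bn_bwd(x, g, plain$mean, plain$var, gated, eps)
  fus <- nucseg:::cpp_bn_bwd(x, g, fused$mean, fused$var, dy, eps,
                             y = fused$y, relu = TRUE)
  expect_equal(fus$dx, ref$dx, tolerance = 1e-12)
  expect_equal(fus$dgamma, ref$dgamma, tolerance = 1e-12)
})

test_that("max pool records argmax indices that unpooling scatters back", {
  set.seed(5)
  x <- array(rnorm(5 * 7 * 2 * 1), c(5, 7, 2, 1))  # odd sizes -> floor
  mp <- nucseg:::cpp_maxpool_fwd(x)
  expect_equal(dim(mp$y), c(2L, 3L, 2L, 1L))
  for (c in 1:2) for (i in 1:2) for (j in 1:3) {
    blk <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, 1]
    expect_equal(mp$y[i, j, c, 1], max(blk))
  }
  up <- nucseg:::cpp_maxunpool_fwd(mp$y, mp$idx, 5, 7)
  expect_equal(dim(up), c(5L, 7L, 2L, 1L))
  expect_equal(sum(up != 0), sum(mp$y != 0))
  expect_equal(sort(up[up != 0]), sort(mp$y[mp$y != 0]))
  # pool backward routes gradient to the argmax position only
  dy <- array(rnorm(length(mp$y)), dim(mp$y))
  dx <- nucseg:::cpp_maxpool_bwd(dy, mp$idx, 5, 7)
  expect_equal(sum(dx), sum(dy), tolerance = 1e-12)
  # unpool backward gathers from the scattered positions
  dup <- array(rnorm(5 * 7 * 2), c(5, 7, 2, 1))
  dg <- nucseg:::cpp_maxunpool_bwd(dup, mp$idx, 2, 3)
  expect_equal(dim(dg), dim(mp$y))
})

test_that("skip addition is the identity-mapping element-wise sum", {
  a <- array(c(1, 3, 2, 4), c(2, 2, 1))
  t <- array(c(10, 0, 0, 10), c(2, 2, 1))
  expect_equal(apply_skip(a, array(0, c(2, 2, 1)), "add"), a)
  expect_equal(apply_skip(array(0, c(2, 2, 1)), t, "add"), t)
  expect_equal(as.numeric(apply_skip(a, t, "add")), c(11, 3, 2, 14))
  expect_error(apply_skip(a, array(0, c(3, 2, 1)), "add"), "mismatch")
  cc <- apply_skip(a, t, "concat")
  expect_equal(dim(cc), c(2L, 2L, 2L))
})

test_that("built network has 20 conv layers, 4 pools, and 4 identity skips", {
  net <- build_rsnn(rsnn_spec(width_multiplier = 1 / 8), seed = 1)
  expect_identical(n_conv_layers(net), 20L)
  expect_identical(n_skip_connections(net), 4L)
  kinds <- vapply(net$spec$layers, `[[`, "", "kind")
  expect_identical(sum(kinds == "maxpool"), 4L)
  expect_identical(sum(kinds == "unpool"), 4L)
  none <- build_rsnn(rsnn_spec(width_multiplier = 1 / 8, skip_mode = "none"),
                     seed = 1)
  expect_identical(n_conv_layers(none), 20L)
  expect_identical(n_skip_connections(none), 0L)
})

test_that("forward output is a softmax field of the input size", {
  net <- build_rsnn(rsnn_spec(width_multiplier = 1 / 16), seed = 7)
  for (hw in list(c(64, 64), c(80, 48))) {
    x <- array(runif(hw[1] * hw[2] * 3), c(hw[1], hw[2], 3, 1))
    p <- rsnn_forward(net, x)$probs
    expect_equal(dim(p), c(hw, 2L, 1L))
    expect_equal(apply(p, c(1, 2, 4), sum),
                 array(1, c(hw, 1)), tolerance = 1e-6)
  }
})

test_that("forward is deterministic for a fixed seed and input", {
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  p1 <- rsnn_forward(build_rsnn(rsnn_spec(1 / 16), seed = 9), x)$probs
  p2 <- rsnn_forward(build_rsnn(rsnn_spec(1 / 16), seed = 9), x)$probs
  expect_identical(p1, p2)
})

test_that("gradient reaches every conv weight and BN parameter", {
  net <- build_rsnn(rsnn_spec(width_multiplier = 1 / 16), seed = 11)
  set.seed(12)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  y <- array(rbinom(64 * 64 * 2, 1, 0.3), c(64, 64, 1, 2))
  f <- rsnn_forward(net, x, training = TRUE)
  lg <- nucseg:::batch_loss_grad(f$probs, y, train_config())
  g <- rsnn_backward(net, f$cache, lg$dlogits)
  expect_setequal(names(g), names(net$params))
  for (nm in names(g)) {
    expect_gt(sum(abs(g[[nm]]$w)), 0)
    expect_gt(sum(abs(g[[nm]]$gamma)), 0)
    expect_gt(sum(abs(g[[nm]]$beta)), 0)
    # conv bias feeds batch norm, which is shift-invariant
    expect_equal(sum(abs(g[[nm]]$b)), 0)
  }
})

test_that("predict_mask thresholds at the argmax with background ties", {
  net <- build_rsnn(rsnn_spec(width_multiplier = 1 / 16), seed = 13)
  img <- synth_sample(c(64, 64), 4, seed = 3)$image
  m <- predict_mask(net, img)
  expect_true(all(m %in% c(0L, 1L)))
  expect_equal(dim(m), c(64L, 64L))
})

test_that("network checkpoints round-trip through save/load", {
  net <- build_rsnn(rsnn_spec(width_multiplier = 1 / 16), seed = 15)
  f <- tempfile(fileext = ".rds")
  save_network(net, f)
  back <- load_network(f)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  expect_identical(rsnn_forward(net, x)$probs, rsnn_forward(back, x)$probs)
})
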