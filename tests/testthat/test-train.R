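test_that("cross-entropy loss matches closed-form hand evaluations", {
  expect_lt(cross_entropy_loss(1, 1 - 1e-7), 1e-6)
  expect_equal(cross_entropy_loss(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(cross_entropy_loss(c(1, 0), c(0.9, 0.2)),
               -0.5 * (log(0.9) + log(0.8)), tolerance = 1e-9)
  expect_error(cross_entropy_loss(numeric(0), numeric(0)), "empty")
  # non-negative and strictly decreasing in h for y = 1
  hs <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(hs, function(h) cross_entropy_loss(1, h), 0)
  expect_true(all(ls >= 0))
  expect_true(all(diff(ls) < 0))
})

test_that("Dice and focal losses behave at their boundary cases", {
  y <- c(1, 1, 0, 0)
  expect_lt(dice_loss(y, y), 1e-6)
  expect_gt(dice_loss(c(1, 1, 0, 0), c(0, 0, 0, 0)), 1 - 1e-6)
  # focal with gamma = 0, alpha = 1 degenerates to cross-entropy
  h <- c(0.8, 0.6, 0.3, 0.1)
  expect_equal(focal_loss(y, h, gamma = 0, alpha = 1),
               cross_entropy_loss(y, h), tolerance = 1e-9)
  expect_error(dice_loss(numeric(0), numeric(0)), "empty")
  expect_error(focal_loss(numeric(0), numeric(0)), "empty")
})

test_that("one Adam step reproduces a hand-computed update", {
  # single parameter w = 2, grad = 4, lr = 0.1
  up <- adam_step(2, 4, NULL, lr = 0.1)
  # m = 0.4, v = 0.016; mhat = 4, vhat = 16 after bias correction
  expect_equal(up$state$m, 0.4)
  expect_equal(up$state$v, 0.016)
  expect_equal(up$param, 2 - 0.1 * 4 / (4 + 1e-8), tolerance = 1e-12)
  # second step with grad 2
  up2 <- adam_step(up$param, 2, up$state, lr = 0.1)
  m2 <- 0.9 * 0.4 + 0.1 * 2
  v2 <- 0.999 * 0.016 + 0.001 * 4
  expect_equal(up2$param,
               up$param - 0.1 * (m2 / (1 - 0.9^2)) /
                 (sqrt(v2 / (1 - 0.999^2)) + 1e-8), tolerance = 1e-12)
})

test_that("global-norm clipping rescales to the threshold", {
  g <- list(a = list(w = c(3, 4), b = 0, gamma = 0, beta = 0))
  cl <- nucseg:::clip_gradients(g, 1, "global_l2")
  expect_equal(sqrt(sum(nucseg:::flatten_grads(cl)^2)), 1, tolerance = 1e-12)
  # below the threshold nothing changes
  expect_identical(nucseg:::clip_gradients(g, 10, "global_l2"), g)
  el <- nucseg:::clip_gradients(g, 3.5, "element")
  expect_equal(el$a$w, c(3, 3.5))
})

test_that("loss-gradient pairs are consistent for every loss family", {
  set.seed(21)
  probs <- array(0, c(4, 4, 2, 1))
  p2 <- matrix(runif(16, 0.1, 0.9), 4)
  probs[, , 2, ] <- p2; probs[, , 1, ] <- 1 - p2
  labels <- array(rbinom(16, 1, 0.5), c(4, 4, 1, 1))
  logits <- array(0, c(4, 4, 2, 1))
  logits[, , 2, ] <- log(p2); logits[, , 1, ] <- log(1 - p2)
  for (lname in c("cross_entropy", "dice", "focal")) {
    cfg <- train_config(loss = lname)
    lg <- nucseg:::batch_loss_grad(probs, labels, cfg)
    # finite differences through the softmax on a few logits
    for (k in sample(32, 4)) {
      h <- 1e-6
      lp <- logits; lp[k] <- lp[k] + h
      pp <- nucseg:::softmax_channels(lp)
      lm <- logits; lm[k] <- lm[k] - h
      pm <- nucseg:::softmax_channels(lm)
      num <- (nucseg:::batch_loss_grad(pp, labels, cfg)$loss -
                nucseg:::batch_loss_grad(pm, labels, cfg)$loss) / (2 * h)
      expect_equal(lg$dlogits[k], num, tolerance = 1e-4)
    }
  }
})

test_that("a few hundred iterations fit one tiny tile", {
  tiles <- tiny_tiles(2, hw = 64, seed = 6)
  net <- build_rsnn(rsnn_spec(width_multiplier = 1 / 8), seed = 30)
  cfg <- train_config(epochs = 60, batch_size = 2, seed = 30)
  fit <- train_rsnn(net, tiles$images, tiles$masks, cfg)
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
  expect_equal(nrow(fit$history), 60)
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("training is deterministic under a fixed seed", {
  tiles <- tiny_tiles(2, hw = 64, seed = 7)
  run <- function() {
    net <- build_rsnn(rsnn_spec(width_multiplier = 1 / 16), seed = 31)
    train_rsnn(net, tiles$images, tiles$masks,
               train_config(epochs = 3, batch_size = 2, seed = 31))$history$loss
  }
  expect_identical(run(), run())
})

test_that("training curves are serialized as CSV", {
  h <- data.frame(epoch = 1:2, iterations = c(5, 10), loss = c(0.5, 0.4),
                  pixel_accuracy = c(0.8, 0.9))
  f <- tempfile(fileext = ".csv")
  write_history(h, f)
  expect_equal(read.csv(f), h)
})
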