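#' Pixel-wise binary cross-entropy loss
#'
#' Mean over pixels of `-[y*ln(h) + (1-y)*ln(1-h)]`, where `h` is the
#' predicted nucleus probability and `y` the binary target. Probabilities are
#' clamped to `[eps, 1-eps]`.
#'
#' @param y numeric vector/array of binary targets in `{0, 1}`.
#' @param h numeric vector/array of predicted probabilities, same length.
#' @param eps clamping epsilon (default 1e-7).
#' @return non-negative scalar.
#' @export
cross_entropy_loss <- function(y, h, eps = 1e-7) {
  if (length(y) == 0L) stop("empty batch")
  stopifnot(length(y) == length(h), all(y %in% c(0, 1)))
  h <- pmin(pmax(as.numeric(h), eps), 1 - eps)
  y <- as.numeric(y)
  -mean(y * log(h) + (1 - y) * log(1 - h))
}

#' Soft Dice loss
#'
#' `1 - 2|P.G| / (|P| + |G|)` with additive smoothing, on soft predictions.
#'
#' @inheritParams cross_entropy_loss
#' @param smooth smoothing constant added to numerator and denominator.
#' @return scalar in `[0, 1]` (up to smoothing).
#' @export
dice_loss <- function(y, h, smooth = 1e-7) {
  if (length(y) == 0L) stop("empty batch")
  stopifnot(length(y) == length(h))
  y <- as.numeric(y); h <- as.numeric(h)
  1 - (2 * sum(y * h) + smooth) / (sum(y) + sum(h) + smooth)
}

#' Focal loss
#'
#' `-mean(alpha * (1-pt)^gamma * ln(pt))` with `pt` the probability assigned
#' to the true class. With `gamma = 0`, `alpha = 1` it reduces to
#' cross-entropy.
#'
#' @inheritParams cross_entropy_loss
#' @param gamma focusing exponent (default 2).
#' @param alpha class weight on the positive term (default 0.25); the
#'   negative term is weighted `1 - alpha` when `alpha < 1`, or 1 when
#'   `alpha = 1`.
#' @return non-negative scalar.
#' @export
focal_loss <- function(y, h, gamma = 2, alpha = 0.25, eps = 1e-7) {
  if (length(y) == 0L) stop("empty batch")
  stopifnot(length(y) == length(h), all(y %in% c(0, 1)))
  h <- pmin(pmax(as.numeric(h), eps), 1 - eps)
  y <- as.numeric(y)
  a_neg <- if (alpha >= 1) 1 else 1 - alpha
  pt <- ifelse(y == 1, h, 1 - h)
  at <- ifelse(y == 1, alpha, a_neg)
  -mean(at * (1 - pt)^gamma * log(pt))
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with initial learning
#' rate 1e-4, mini-batch 4, L2 regularization 5e-4 (conv weights only),
#' gradient threshold 8 (global L2-norm clipping), 30 epochs, pixel-wise
#' cross-entropy loss over all pixels of the batch.
#'
#' @param learning_rate Adam step size.
#' @param batch_size images per mini-batch.
#' @param l2_regularization L2 penalty coefficient on conv weights.
#' @param gradient_threshold clip the gradient so its norm is at most this;
#'   `Inf` disables clipping.
#' @param clip_mode `"global_l2"` (default) scales the whole gradient vector;
#'   `"element"` clips each component to `[-t, t]`.
#' @param epochs training epochs.
#' @param seed RNG seed controlling shuffling (and initialization when the
#'   trainer builds the network).
#' @param loss one of `"cross_entropy"`, `"dice"`, `"focal"`.
#' @param class_weights optional length-2 weights (background, nucleus) for
#'   the cross-entropy loss; default unweighted.
#' @param focal_gamma,focal_alpha focal-loss parameters.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4,
                         l2_regularization = 5e-4, gradient_threshold = 8,
                         clip_mode = c("global_l2", "element"),
                         epochs = 30, seed = 1L,
                         loss = c("cross_entropy", "dice", "focal"),
                         class_weights = c(1, 1),
                         focal_gamma = 2, focal_alpha = 0.25) {
  clip_mode <- match.arg(clip_mode)
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, batch_size >= 1, l2_regularization >= 0,
            gradient_threshold > 0, epochs >= 1, length(class_weights) == 2L)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 l2_regularization = l2_regularization,
                 gradient_threshold = gradient_threshold,
                 clip_mode = clip_mode, epochs = as.integer(epochs),
                 seed = as.integer(seed), loss = loss,
                 class_weights = as.numeric(class_weights),
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha),
            class = "train_config")
}

# loss value and gradient w.r.t. the 2-channel logits, mean over batch pixels
batch_loss_grad <- function(probs, labels, config) {
  d <- dim(probs)
  M <- d[1] * d[2] * d[4]
  h <- probs[, , 2, , drop = FALSE]  # nucleus probability
  y <- array(labels, dim = dim(h))
  eps <- 1e-7
  hc <- pmin(pmax(h, eps), 1 - eps)
  if (config$loss == "cross_entropy") {
    wts <- ifelse(y == 1, config$class_weights[2], config$class_weights[1])
    loss <- -sum(wts * (y * log(hc) + (1 - y) * log(1 - hc))) / M
    dh <- wts * (hc - y) / (hc * (1 - hc)) / M
  } else if (config$loss == "dice") {
    sm <- 1e-7
    num <- 2 * sum(y * h) + sm
    den <- sum(y) + sum(h) + sm
    loss <- 1 - num / den
    dh <- array((-2 * y * den + num) / den^2, dim = dim(h))
  } else {
    g <- config$focal_gamma; a <- config$focal_alpha
    a_neg <- if (a >= 1) 1 else 1 - a
    pt <- ifelse(y == 1, hc, 1 - hc)
    at <- ifelse(y == 1, a, a_neg)
    loss <- -sum(at * (1 - pt)^g * log(pt)) / M
    dpt <- -at * ((1 - pt)^g / pt - g * (1 - pt)^(g - 1) * log(pt)) / M
    dh <- ifelse(y == 1, dpt, -dpt)
  }
  # chain through the 2-class softmax: h = p2, dlogit2 = dh * h(1-h)
  hh <- h * (1 - h)
  dlog <- array(0, dim = d)
  dlog[, , 2, ] <- dh * hh
  dlog[, , 1, ] <- -dh * hh
  list(loss = loss, dlogits = dlog)
}

flatten_grads <- function(grads) {
  unlist(lapply(grads, function(g) c(g$w, g$b, g$gamma, g$beta)),
         use.names = FALSE)
}

clip_gradients <- function(grads, threshold, mode) {
  if (!is.finite(threshold)) return(grads)
  if (mode == "global_l2") {
    nrm <- sqrt(sum(flatten_grads(grads)^2))
    if (nrm <= threshold) return(grads)
    sc <- threshold / nrm
    lapply(grads, function(g) lapply(g, function(v) v * sc))
  } else {
    lapply(grads, function(g) lapply(g, function(v) pmin(pmax(v, -threshold),
                                                         threshold)))
  }
}

#' Single Adam update
#'
#' Standard bias-corrected Adam on one parameter vector; exposed for testing
#' against a hand-computed update.
#'
#' @param param,grad numeric vectors.
#' @param state list with `m`, `v`, `t` (or `NULL` to initialize).
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @return list with updated `param` and `state`.
#' @export
adam_step <- function(param, grad, state = NULL, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) state <- list(m = 0 * param, v = 0 * param, t = 0L)
  t <- state$t + 1L
  m <- beta1 * state$m + (1 - beta1) * grad
  v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps),
       state = list(m = m, v = v, t = t))
}

#' Train a segmentation network
#'
#' Mini-batch Adam with L2 regularization on conv weights, gradient clipping,
#' and per-epoch loss/pixel-accuracy curves. Deterministic given
#' `config$seed`. Aborts with a diagnostic if the loss becomes NaN.
#'
#' @param network an `rsnn_network` from [build_rsnn()].
#' @param images list of H x W x 3 arrays (0-255 integers or 0-1 numerics);
#'   all images in a batch must share a size.
#' @param masks list of H x W binary matrices (1 = nucleus).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `network` (trained), `history` (data.frame epoch /
#'   iteration count / mean loss / pixel accuracy).
#' @export
train_rsnn <- function(network, images, masks, config = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(network, "rsnn_network"), length(images) >= 1,
            length(images) == length(masks))
  xs <- lapply(images, function(im) {
    x <- if (max(im) > 1) im / 255 else im
    array(as.numeric(x), dim = dim(im))
  })
  ys <- lapply(masks, function(m) (m > 0) * 1)
  set.seed(config$seed)
  adam <- list()
  hist <- list()
  n <- length(xs)
  it <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0; ep_pix <- 0; nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      d1 <- dim(xs[[idx[1]]])
      xb <- array(unlist(xs[idx], use.names = FALSE),
                  dim = c(d1, length(idx)))
      yb <- array(unlist(ys[idx], use.names = FALSE),
                  dim = c(d1[1], d1[2], 1L, length(idx)))
      fwd <- rsnn_forward(network, xb, training = TRUE)
      network <- fwd$network  # carries updated BN running stats
      lg <- batch_loss_grad(fwd$probs, yb, config)
      if (!is.finite(lg$loss))
        stop(sprintf("training aborted: non-finite loss at epoch %d (iteration %d)",
                     ep, it + 1L))
      grads <- rsnn_backward(network, fwd$cache, lg$dlogits)
      if (config$l2_regularization > 0) {
        for (nm in names(grads))
          grads[[nm]]$w <- grads[[nm]]$w +
            config$l2_regularization * network$params[[nm]]$w
      }
      grads <- clip_gradients(grads, config$gradient_threshold, config$clip_mode)
      for (nm in names(grads)) {
        for (fld in c("w", "b", "gamma", "beta")) {
          key <- paste0(nm, ".", fld)
          up <- adam_step(network$params[[nm]][[fld]], grads[[nm]][[fld]],
                          adam[[key]], lr = config$learning_rate)
          network$params[[nm]][[fld]] <- up$param
          adam[[key]] <- up$state
        }
      }
      it <- it + 1L; nb <- nb + 1L
      ep_loss <- ep_loss + lg$loss
      pred <- fwd$probs[, , 2, , drop = FALSE] > fwd$probs[, , 1, , drop = FALSE]
      ep_correct <- ep_correct + sum((pred * 1) == yb)
      ep_pix <- ep_pix + length(yb)
    }
    hist[[ep]] <- data.frame(epoch = ep, iterations = it,
                             loss = ep_loss / nb,
                             pixel_accuracy = ep_correct / ep_pix)
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f  acc %.4f", ep, config$epochs,
                      ep_loss / nb, ep_correct / ep_pix))
  }
  network <- recalibrate_bn(network, xs, config$batch_size)
  list(network = network, history = do.call(rbind, hist))
}

# Precise batch-norm calibration: with frozen weights, replace the running
# statistics by the exact average of batch statistics over the training set.
# The exponential moving average collected during training lags the weights
# (which move every iteration), and inference quality is very sensitive to
# that mismatch.
recalibrate_bn <- function(network, xs, batch_size) {
  n <- length(xs)
  sum_m <- NULL; sum_s <- NULL; total <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    d1 <- dim(xs[[idx[1]]])
    xb <- array(unlist(xs[idx], use.names = FALSE), dim = c(d1, length(idx)))
    f <- rsnn_forward(network, xb, training = TRUE, update_running = FALSE)
    w <- length(idx)
    st_m <- lapply(f$cache$layers, function(cc) cc$mean * w)
    st_s <- lapply(f$cache$layers, function(cc) (cc$var + cc$mean^2) * w)
    if (is.null(sum_m)) {
      sum_m <- st_m; sum_s <- st_s
    } else {
      for (nm in names(st_m)) {
        sum_m[[nm]] <- sum_m[[nm]] + st_m[[nm]]
        sum_s[[nm]] <- sum_s[[nm]] + st_s[[nm]]
      }
    }
    total <- total + w
  }
  for (nm in names(sum_m)) {
    mu <- sum_m[[nm]] / total
    network$params[[nm]]$running_mean <- mu
    network$params[[nm]]$running_var <- pmax(sum_s[[nm]] / total - mu^2, 0)
  }
  network
}

#' Write training curves to CSV
#' @param history the `history` data.frame from [train_rsnn()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
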