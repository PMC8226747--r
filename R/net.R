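#' Build a trainable network from an architecture spec
#'
#' Allocates conv weights (He fan-in-scaled normal, seeded), zero biases, and
#' batch-norm scale/shift (1, 0) with running statistics for inference.
#' The network is trained from scratch; there is no pretrained initialization.
#'
#' @param spec an [rsnn_spec()].
#' @param seed integer RNG seed for weight initialization.
#' @return An `rsnn_network`: list with `spec` and `params` (one entry per
#'   parameterized layer: `w` 3x3xCinxCout, `b`, `gamma`, `beta`,
#'   `running_mean`, `running_var`).
#' @export
build_rsnn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "rsnn_spec"))
  set.seed(seed)
  params <- list()
  for (l in spec$layers) {
    if (!l$kind %in% c("conv", "classifier")) next
    cin <- l$in_channels; cout <- l$out_channels
    fan_in <- 9 * cin
    w <- array(stats::rnorm(9 * cin * cout, sd = sqrt(2 / fan_in)),
               dim = c(3L, 3L, cin, cout))
    params[[l$name]] <- list(
      w = w, b = numeric(cout),
      gamma = rep(1, cout), beta = numeric(cout),
      running_mean = numeric(cout), running_var = rep(1, cout))
  }
  structure(list(spec = spec, params = params), class = "rsnn_network")
}

#' Number of convolution layers in a built network
#' @param network an `rsnn_network`.
#' @return integer.
#' @export
n_conv_layers <- function(network) {
  stopifnot(inherits(network, "rsnn_network"))
  length(network$params)
}

#' Number of skip connections in a built network
#' @param network an `rsnn_network`.
#' @return integer.
#' @export
n_skip_connections <- function(network) {
  stopifnot(inherits(network, "rsnn_network"))
  sum(vapply(network$spec$layers,
             function(l) identical(l$skip_role, "sink"), logical(1)))
}

#' Apply a skip connection
#'
#' `add` mode is the identity-mapping element-wise sum of the decoder's local
#' features and the transferred encoder features (no learned projection);
#' `concat` stacks them along the channel axis.
#'
#' @param local,transferred numeric arrays (H x W x C or H x W x C x N).
#' @param mode `"add"` or `"concat"`.
#' @return combined array.
#' @export
apply_skip <- function(local, transferred, mode = c("add", "concat")) {
  mode <- match.arg(mode)
  dl <- dim(local); dt <- dim(transferred)
  if (mode == "add") {
    if (!identical(dl, dt)) stop("skip shape mismatch: add requires identical shapes")
    local + transferred
  } else {
    if (!identical(dl[-3], dt[-3]) || !identical(dl[1:2], dt[1:2]))
      stop("skip shape mismatch: concat requires identical H, W")
    if (length(dl) == 3L) {
      array(c(local, transferred), dim = c(dl[1], dl[2], dl[3] + dt[3]))
    } else {
      out <- array(0, dim = c(dl[1], dl[2], dl[3] + dt[3], dl[4]))
      out[, , seq_len(dl[3]), ] <- local
      out[, , dl[3] + seq_len(dt[3]), ] <- transferred
      out
    }
  }
}

as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Forward pass
#'
#' Runs a batch through the network. In training mode batch-norm uses batch
#' statistics (updating running averages when `update_running`); in inference
#' mode it uses the stored running statistics. The network is fully
#' convolutional: any input whose shape survives [trace_shapes()] is accepted.
#'
#' @param network an `rsnn_network`.
#' @param x numeric array H x W x 3 x N (or H x W x 3) of inputs scaled to
#'   `[0, 1]`.
#' @param training logical; use batch statistics and keep a backward cache.
#' @param update_running update BN running statistics (training only).
#' @return list with `probs` (H x W x n_classes x N softmax probabilities),
#'   `logits`, and (when `training`) `cache` for [rsnn_backward()].
#' @export
rsnn_forward <- function(network, x, training = FALSE, update_running = training) {
  stopifnot(inherits(network, "rsnn_network"))
  x <- as_batch(x)
  spec <- network$spec
  pool_idx <- vector("list", 4L)
  pool_pre <- vector("list", 4L)
  skips <- list()
  cache <- if (training) list() else NULL
  for (li in seq_along(spec$layers)) {
    l <- spec$layers[[li]]
    if (l$kind %in% c("conv", "classifier")) {
      p <- network$params[[l$name]]
      xin <- x
      co <- cpp_conv3x3_fwd(xin, p$w, p$b)
      bn <- cpp_bn_fwd(co, p$gamma, p$beta, BN_EPS, training,
                       p$running_mean, p$running_var, relu = (l$kind == "conv"))
      if (training && update_running) {
        n_eff <- prod(dim(co)[c(1, 2, 4)])
        ub <- if (n_eff > 1) n_eff / (n_eff - 1) else 1
        network$params[[l$name]]$running_mean <-
          (1 - BN_MOMENTUM) * p$running_mean + BN_MOMENTUM * bn$mean
        network$params[[l$name]]$running_var <-
          (1 - BN_MOMENTUM) * p$running_var + BN_MOMENTUM * bn$var * ub
      }
      y <- bn$y  # ReLU fused into the BN kernel; classifier feeds softmax
      if (training)
        cache[[l$name]] <- list(x = xin, conv = co, mean = bn$mean,
                                var = bn$var, relu = (l$kind == "conv"),
                                y = if (l$kind == "conv") y else NULL)
      x <- y
      if (identical(l$skip_role, "source")) skips[[l$skip_tag]] <- x
    } else if (l$kind == "maxpool") {
      pool_pre[[l$pool_pair]] <- dim(x)[1:2]
      mp <- cpp_maxpool_fwd(x)
      pool_idx[[l$pool_pair]] <- mp$idx
      x <- mp$y
    } else if (l$kind == "unpool") {
      hw <- pool_pre[[l$pool_pair]]
      x <- cpp_maxunpool_fwd(x, pool_idx[[l$pool_pair]], hw[1], hw[2])
    } else if (l$kind == "add") {
      x <- apply_skip(x, skips[[l$skip_tag]], "add")
    } else if (l$kind == "concat") {
      x <- apply_skip(x, skips[[l$skip_tag]], "concat")
    }
  }
  logits <- x
  probs <- softmax_channels(logits)
  out <- list(probs = probs, logits = logits)
  if (training) {
    out$cache <- list(layers = cache, pool_idx = pool_idx, pool_pre = pool_pre,
                      input_dim = NULL)
    # updated running stats live in `network`; return it too
    out$network <- network
  }
  out
}

# numerically stable softmax over the channel axis of H x W x C x N
softmax_channels <- function(logits) {
  d <- dim(logits)
  zm <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = d[3])
  zm <- zm - do.call(pmax, lapply(seq_len(ncol(zm)), function(j) zm[, j]))
  e <- exp(zm)
  p <- e / rowSums(e)
  aperm(array(p, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
}

#' Backward pass
#'
#' Backpropagates a gradient with respect to the logits through the network,
#' returning per-parameter gradients. Conv biases feeding batch norm receive
#' zero gradient (batch norm is invariant to an input shift); they remain in
#' the parameter account.
#'
#' @param network an `rsnn_network`.
#' @param cache the `cache` element returned by [rsnn_forward()] with
#'   `training = TRUE`.
#' @param dlogits gradient of the loss w.r.t. the logits (same shape).
#' @return named list (by layer) of gradients `w`, `b`, `gamma`, `beta`.
#' @export
rsnn_backward <- function(network, cache, dlogits) {
  spec <- network$spec
  grads <- list()
  dskip <- list()  # accumulated gradient flowing into each skip source
  dx <- as_batch(dlogits)
  for (li in rev(seq_along(spec$layers))) {
    l <- spec$layers[[li]]
    if (l$kind %in% c("conv", "classifier")) {
      cc <- cache$layers[[l$name]]
      p <- network$params[[l$name]]
      if (identical(l$skip_role, "source") && !is.null(dskip[[l$skip_tag]]))
        dx <- dx + dskip[[l$skip_tag]]
      bw <- cpp_bn_bwd(cc$conv, p$gamma, cc$mean, cc$var, dx, BN_EPS,
                       y = cc$y, relu = cc$relu)
      cb <- cpp_conv3x3_bwd(cc$x, p$w, bw$dx)
      grads[[l$name]] <- list(w = cb$dw, b = numeric(length(p$b)),
                              gamma = bw$dgamma, beta = bw$dbeta)
      dx <- cb$dx
    } else if (l$kind == "maxpool") {
      hw <- cache$pool_pre[[l$pool_pair]]
      dx <- cpp_maxpool_bwd(dx, cache$pool_idx[[l$pool_pair]], hw[1], hw[2])
    } else if (l$kind == "unpool") {
      d <- dim(dx)
      ho <- d[1] %/% 2L; wo <- d[2] %/% 2L
      dx <- cpp_maxunpool_bwd(dx, cache$pool_idx[[l$pool_pair]], ho, wo)
    } else if (l$kind == "add") {
      dskip[[l$skip_tag]] <- dx  # identity: gradient passes to both branches
    } else if (l$kind == "concat") {
      d <- dim(dx)
      half <- d[3] %/% 2L
      dskip[[l$skip_tag]] <- dx[, , half + seq_len(half), , drop = FALSE]
      dx <- dx[, , seq_len(half), , drop = FALSE]
    }
  }
  grads
}

#' Forward pass returning class probabilities
#'
#' @param network an `rsnn_network`.
#' @param image H x W x 3 integer array in `[0, 255]` (a stain-normalized
#'   tile) or an already scaled `[0, 1]` numeric array.
#' @return H x W x n_classes array of per-pixel class probabilities
#'   (channels sum to 1).
#' @export
rsnn_predict_probs <- function(network, image) {
  x <- if (max(image) > 1) image / 255 else image
  dim(x) <- c(dim(x)[1:2], 3L, 1L)
  p <- rsnn_forward(network, x, training = FALSE)$probs
  array(p, dim = dim(p)[1:3])
}

#' Predict a binary nucleus mask
#'
#' Argmax over the two classes; an exact 0.5/0.5 tie is background.
#'
#' @inheritParams rsnn_predict_probs
#' @return H x W integer matrix in `{0, 1}` (1 = nucleus).
#' @export
predict_mask <- function(network, image) {
  p <- rsnn_predict_probs(network, image)
  m <- (p[, , 2] > p[, , 1]) * 1L
  matrix(as.integer(m), nrow = dim(p)[1])
}

#' Save / load network weights
#' @param network an `rsnn_network`.
#' @param path checkpoint file path (RDS).
#' @return `save_network` returns `path` invisibly; `load_network` the network.
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "rsnn_network"))
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "rsnn_network"))
  net
}
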