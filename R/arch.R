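#' Residual-skip segmentation network architecture
#'
#' The network is a 4-block encoder / 4-block decoder. Encoder blocks hold
#' (2, 2, 3, 3) conv+BN+ReLU units of width (64, 128, 256, 512); each block
#' ends in a 2x2 stride-2 max pool that records its argmax indices. The
#' decoder mirrors the encoder with max-unpooling. Four residual skip
#' connections carry the output of the FIRST conv unit of each encoder block
#' and are added element-wise (identity mapping, no learned projection) to the
#' output of the second-to-last conv unit of the matching decoder block,
#' before the block's final conv. The bottleneck of a 500x500 input is
#' 31x31x512. 20 conv layers in total (10 encoder, 10 decoder including the
#' final 2-channel classifier conv, which is followed by BN and softmax).
#'
#' @name rsnn-architecture
NULL

#' Build the architecture specification
#'
#' @param width_multiplier positive scaling applied to every hidden channel
#'   count (input stays 3, output stays `n_classes`). Default 1 reproduces the
#'   reference architecture. Fractional widths (e.g. 1/4) give desk-scale
#'   networks with the same topology.
#' @param skip_mode `"add"` (element-wise identity addition, default),
#'   `"none"` (skips removed), or `"concat"` (channel concatenation, which
#'   widens the following conv).
#' @param n_classes number of output classes (default 2: background, nucleus).
#' @return An `rsnn_spec`: list with `layers` (ordered layer records),
#'   `skip_mode`, `width_multiplier`, `n_classes`.
#' @export
rsnn_spec <- function(width_multiplier = 1, skip_mode = c("add", "none", "concat"),
                      n_classes = 2) {
  skip_mode <- match.arg(skip_mode)
  stopifnot(width_multiplier > 0, n_classes >= 2)
  base <- list(c(64, 64), c(128, 128), c(256, 256, 256), c(512, 512, 512))
  ch <- lapply(base, function(v) {
    s <- round(v * width_multiplier)
    if (any(s < 1)) stop("width_multiplier yields zero channels")
    s
  })
  layers <- list()
  add <- function(name, kind, inC = NA, outC = NA, skip_tag = NA_character_,
                  skip_role = NA_character_, pool_pair = NA_integer_) {
    layers[[length(layers) + 1L]] <<- list(
      name = name, kind = kind, kernel = if (kind %in% c("conv", "classifier"))
        c(3L, 3L) else if (kind %in% c("maxpool", "unpool")) c(2L, 2L) else NULL,
      in_channels = inC, out_channels = outC,
      skip_tag = skip_tag, skip_role = skip_role, pool_pair = pool_pair)
  }
  use_skips <- skip_mode != "none"
  # encoder
  inC <- 3L
  for (b in 1:4) {
    for (u in seq_along(ch[[b]])) {
      outC <- ch[[b]][u]
      add(sprintf("EConvBR-%d_%d", b, u), "conv", inC, outC,
          skip_tag = if (u == 1L && use_skips) sprintf("RC-%d", b) else NA_character_,
          skip_role = if (u == 1L && use_skips) "source" else NA_character_)
      inC <- outC
    }
    add(sprintf("Pool-%d", b), "maxpool", inC, inC, pool_pair = b)
  }
  # decoder
  for (b in 4:1) {
    nu <- length(ch[[b]])
    add(sprintf("Unpool-%d", b), "unpool", inC, inC, pool_pair = b)
    for (u in nu:1) {
      last_unit <- (u == 1L)
      outC <- if (!last_unit) ch[[b]][u] else if (b > 1) ch[[b - 1]][length(ch[[b - 1]])] else n_classes
      if (u == 2L && use_skips) {
        # conv, then the skip sink between this conv and the block's final conv
        add(sprintf("DConvBR-%d_%d", b, u), "conv", inC, outC)
        inC <- outC
        add(sprintf("Add-%d", b), if (skip_mode == "add") "add" else "concat",
            inC, if (skip_mode == "concat") 2L * inC else inC,
            skip_tag = sprintf("RC-%d", b), skip_role = "sink")
        if (skip_mode == "concat") inC <- 2L * inC
      } else {
        kind <- if (b == 1L && last_unit) "classifier" else "conv"
        add(sprintf("DConvBR-%d_%d", b, u), kind, inC, outC)
        inC <- outC
      }
    }
  }
  structure(list(layers = layers, skip_mode = skip_mode,
                 width_multiplier = width_multiplier, n_classes = n_classes),
            class = "rsnn_spec")
}

#' Exact trainable-parameter account
#'
#' Conv layers contribute `kh*kw*C_in*C_out + C_out` (weights + bias); each
#' conv (including the classifier) is followed by batch norm contributing
#' `2*C_out` (scale + shift). Pooling, unpooling, softmax, and identity skip
#' additions are parameter-free; concatenation skips change the following
#' conv's input width and therefore its count.
#'
#' @param spec an [rsnn_spec()].
#' @return A `data.frame` with one row per parameterized layer
#'   (`name`, `in_channels`, `out_channels`, `conv_params`, `bn_params`) and
#'   attribute `total`; also accessible via `sum()` of the two columns.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "rsnn_spec"))
  rows <- Filter(function(l) l$kind %in% c("conv", "classifier"), spec$layers)
  df <- data.frame(
    name = vapply(rows, `[[`, "", "name"),
    in_channels = vapply(rows, function(l) as.integer(l$in_channels), 0L),
    out_channels = vapply(rows, function(l) as.integer(l$out_channels), 0L),
    stringsAsFactors = FALSE)
  df$conv_params <- 9 * df$in_channels * df$out_channels + df$out_channels
  df$bn_params <- 2 * df$out_channels
  attr(df, "total") <- sum(df$conv_params) + sum(df$bn_params)
  df
}

#' Total trainable parameters
#' @param spec an [rsnn_spec()].
#' @return integer-valued scalar.
#' @export
total_parameters <- function(spec) attr(count_parameters(spec), "total")

#' Trace feature-map shapes through the network
#'
#' Pooling halves spatial dimensions with floor rounding (125 -> 62); each
#' unpool restores the recorded pre-pool size of its paired pool (62 -> 125).
#'
#' @param spec an [rsnn_spec()].
#' @param input_hw length-2 integer (H, W), both >= 16.
#' @return `data.frame` with columns `name`, `height`, `width`, `channels`.
#' @export
trace_shapes <- function(spec, input_hw) {
  stopifnot(inherits(spec, "rsnn_spec"), length(input_hw) == 2L)
  h <- as.integer(input_hw[1]); w <- as.integer(input_hw[2])
  if (h < 16L || w < 16L)
    stop("input too small for 4 pooling stages (need H, W >= 16)")
  pre <- vector("list", 4L)
  out <- list()
  for (l in spec$layers) {
    if (l$kind == "maxpool") {
      pre[[l$pool_pair]] <- c(h, w)
      h <- h %/% 2L; w <- w %/% 2L
      if (h < 1L || w < 1L) stop("input too small for 4 pooling stages")
      c_out <- l$out_channels
    } else if (l$kind == "unpool") {
      h <- pre[[l$pool_pair]][1]; w <- pre[[l$pool_pair]][2]
      c_out <- l$out_channels
    } else {
      c_out <- l$out_channels
    }
    out[[length(out) + 1L]] <- data.frame(name = l$name, height = h, width = w,
                                          channels = c_out)
  }
  do.call(rbind, out)
}

#' Serialize / deserialize an architecture spec to YAML
#' @param spec an [rsnn_spec()].
#' @param path file path.
#' @return `spec_to_yaml` returns `path` invisibly; `spec_from_yaml` an
#'   [rsnn_spec()].
#' @export
spec_to_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "rsnn_spec"))
  yaml::write_yaml(list(width_multiplier = spec$width_multiplier,
                        skip_mode = spec$skip_mode,
                        n_classes = spec$n_classes), path)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @export
spec_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  rsnn_spec(width_multiplier = y$width_multiplier, skip_mode = y$skip_mode,
            n_classes = y$n_classes)
}
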