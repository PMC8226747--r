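#' Synthetic H&E nuclei simulator
#'
#' Renders elliptical nucleus instances through the Beer-Lambert two-stain
#' optical-density model: per-pixel hematoxylin and eosin concentrations are
#' mixed through a (per-slide perturbed) stain basis, exponentiated to RGB
#' transmitted intensities, and corrupted with additive Gaussian noise. The
#' paired instance masks are exact: a pixel belongs to a nucleus iff its
#' center satisfies the ellipse inequality. The generator is a pure function
#' of its parameters and seed, which makes stain-vector recovery, training,
#' and metric evaluation testable without any real-slide download.
#'
#' @name synthetic-data
NULL

#' A per-slide rendering style
#'
#' @param basis a [stain_basis()]; default the canonical reference basis
#'   perturbed by `basis_jitter_sd`.
#' @param basis_jitter_sd per-component Gaussian jitter of the stain vectors
#'   (re-normalized afterwards).
#' @param nucleus_h_mean mean hematoxylin concentration inside nuclei (drawn
#'   once per call from `U(0.9, 1.4)` when `NULL`).
#' @param background_e_mean mean eosin concentration of the background (drawn
#'   from `U(0.4, 0.8)` when `NULL`); the lognormal texture tail emulates
#'   dense collagen-like regions.
#' @param texture_sd lognormal sigma of the per-pixel concentration jitter.
#' @param gain per-slide intensity gain on all concentrations (drawn from
#'   `U(0.85, 1.25)` when `NULL`).
#' @param noise_sd additive Gaussian sensor noise, intensity units.
#' @param seed RNG seed used for the randomly drawn style components.
#' @return a `slide_style` list.
#' @export
slide_style <- function(basis = NULL, basis_jitter_sd = 0.05,
                        nucleus_h_mean = NULL, background_e_mean = NULL,
                        texture_sd = NULL, gain = NULL, noise_sd = 3,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(basis)) {
    ref <- reference_he_basis()
    basis <- stain_basis(
      ref$hematoxylin + stats::rnorm(3, sd = basis_jitter_sd),
      ref$eosin + stats::rnorm(3, sd = basis_jitter_sd))
  }
  structure(list(
    basis = basis,
    nucleus_h_mean = if (is.null(nucleus_h_mean)) stats::runif(1, 0.9, 1.4)
      else nucleus_h_mean,
    background_e_mean = if (is.null(background_e_mean)) stats::runif(1, 0.4, 0.8)
      else background_e_mean,
    nucleus_e_frac = 0.25,     # nuclei retain some eosin
    background_h = 0.03,       # faint hematoxylin haze in background
    texture_sd = if (is.null(texture_sd)) 0.4 else texture_sd,
    gain = if (is.null(gain)) stats::runif(1, 0.85, 1.25) else gain,
    noise_sd = noise_sd), class = "slide_style")
}

#' Sample a nucleus layout and exact instance mask
#'
#' Rotated ellipses with centers uniform on the canvas, semi-axes
#' `U(semi_axes[1], semi_axes[2])`, rotation `U(0, pi)`. A candidate nucleus
#' is rejected when more than `overlap_fraction` of its pixels intersect
#' already placed nuclei, or (when `min_gap > 0`) when its `min_gap`-expanded
#' outline touches an existing nucleus. Overlapping pixels belong to the
#' later instance.
#'
#' @param canvas length-2 integer (H, W), both >= 64.
#' @param n_nuclei integer count, or with `poisson = TRUE` the rate of a
#'   Poisson draw.
#' @param overlap_fraction maximum allowed pairwise pixel-overlap fraction.
#' @param seed RNG seed.
#' @param semi_axes range (pixels) for each semi-axis.
#' @param min_gap minimum separation (pixels) enforced between nuclei.
#' @param poisson draw the count from `Poisson(n_nuclei)`.
#' @param max_tries placement attempts per nucleus before giving up.
#' @return list with `mask` (H x W integer instance mask) and `shapes`
#'   (data.frame `row`, `col`, `a`, `b`, `theta`).
#' @export
sample_layout <- function(canvas, n_nuclei, overlap_fraction = 0, seed = 1L,
                          semi_axes = c(4, 10), min_gap = 2, poisson = FALSE,
                          max_tries = 200L) {
  stopifnot(length(canvas) == 2L, all(canvas >= 64), overlap_fraction >= 0,
            overlap_fraction < 1)
  set.seed(seed)
  H <- canvas[1]; W <- canvas[2]
  n <- if (poisson) stats::rpois(1, n_nuclei) else as.integer(n_nuclei)
  mask <- matrix(0L, H, W)
  shapes <- list()
  placed <- 0L
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      a <- stats::runif(1, semi_axes[1], semi_axes[2])
      b <- stats::runif(1, semi_axes[1], semi_axes[2])
      th <- stats::runif(1, 0, pi)
      r0 <- stats::runif(1, 1, H); c0 <- stats::runif(1, 1, W)
      px <- ellipse_pixels(r0, c0, a, b, th, H, W)
      if (length(px) < 4L) next
      inter <- sum(mask[px] > 0)
      if (inter / length(px) > overlap_fraction) next
      if (min_gap > 0 && overlap_fraction == 0) {
        gx <- ellipse_pixels(r0, c0, a + min_gap, b + min_gap, th, H, W)
        if (any(mask[gx] > 0)) next
      }
      placed <- placed + 1L
      mask[px] <- placed
      shapes[[placed]] <- data.frame(row = r0, col = c0, a = a, b = b,
                                     theta = th)
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place ", n, " nuclei; lower the density or overlap constraints")
  }
  # overlap reassignment can empty an earlier instance; compact labels
  if (placed > 0L) {
    ids <- sort(unique(mask[mask > 0]))
    if (length(ids) < placed) {
      remap <- integer(placed); remap[ids] <- seq_along(ids)
      mask[mask > 0] <- remap[mask[mask > 0]]
      shapes <- shapes[ids]
    }
  }
  list(mask = mask,
       shapes = if (placed > 0) do.call(rbind, shapes) else
         data.frame(row = numeric(), col = numeric(), a = numeric(),
                    b = numeric(), theta = numeric()))
}

# derive a child seed inside the 32-bit range (Lehmer-style mixing)
mix_seed <- function(seed, salt) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + salt) %% 2147483647)
}

# pixel centers (integer row/col) inside a rotated ellipse
ellipse_pixels <- function(r0, c0, a, b, theta, H, W) {
  rmax <- max(a, b)
  rows <- max(1L, floor(r0 - rmax)):min(H, ceiling(r0 + rmax))
  cols <- max(1L, floor(c0 - rmax)):min(W, ceiling(c0 + rmax))
  dr <- rep(rows - r0, times = length(cols))
  dc <- rep(cols - c0, each = length(rows))
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  ri <- rep(rows, times = length(cols))[inside]
  ci <- rep(cols, each = length(rows))[inside]
  ri + (ci - 1L) * H
}

#' Render an instance mask as an H&E tile
#'
#' Inside nuclei: hematoxylin around the style's nucleus mean with per-nucleus
#' and per-pixel lognormal jitter, plus a fraction of the background eosin.
#' Background: lognormal eosin texture plus a faint hematoxylin haze.
#' OD = c_h * h + c_e * e through the style basis; I = I0 * 10^(-OD), plus
#' Gaussian noise, rounded and clipped to `[0, 255]`.
#'
#' @param mask H x W integer instance mask.
#' @param style a [slide_style()].
#' @param i0 transmitted light intensity.
#' @param seed RNG seed.
#' @return H x W x 3 integer array.
#' @export
render_he <- function(mask, style, i0 = 240, seed = 1L) {
  stopifnot(inherits(style, "slide_style"))
  set.seed(seed)
  H <- nrow(mask); W <- ncol(mask)
  npix <- H * W
  sdlog <- style$texture_sd
  ce <- stats::rlnorm(npix, log(style$background_e_mean), sdlog)
  ch <- rep(style$background_h, npix) *
    stats::rlnorm(npix, 0, 0.25)
  K <- max(mask)
  if (K > 0) {
    per_nuc <- style$nucleus_h_mean * stats::rlnorm(K, 0, 0.15)
    inside <- which(mask > 0)
    ch[inside] <- per_nuc[mask[inside]] * stats::rlnorm(length(inside), 0, 0.15)
    ce[inside] <- ce[inside] * style$nucleus_e_frac
  }
  conc <- cbind(ch, ce) * style$gain
  B <- rbind(style$basis$hematoxylin, style$basis$eosin)  # 2 x 3
  od <- conc %*% B
  I <- i0 * 10^(-od) + stats::rnorm(npix * 3, sd = style$noise_sd)
  I <- round(I)
  I[I < 0] <- 0; I[I > 255] <- 255
  out <- array(as.integer(I), dim = c(H, W, 3L))
  out
}

#' Generate a synthetic tile + mask
#'
#' Convenience wrapper: layout, style, and rendering from a single seed.
#'
#' @param canvas length-2 (H, W).
#' @param n_nuclei expected nucleus count (Poisson rate when `poisson`).
#' @param seed RNG seed.
#' @param style optional [slide_style()]; a fresh one (seeded) otherwise.
#' @param poisson draw the count from a Poisson distribution.
#' @param i0 transmitted light intensity.
#' @param ... forwarded to [sample_layout()].
#' @return list `image`, `mask`, `shapes`, `style`.
#' @export
synth_sample <- function(canvas, n_nuclei, seed = 1L, style = NULL,
                         poisson = TRUE, i0 = 240, ...) {
  if (is.null(style)) style <- slide_style(seed = mix_seed(seed, 17))
  lay <- sample_layout(canvas, n_nuclei, seed = seed, poisson = poisson, ...)
  img <- render_he(lay$mask, style, i0 = i0, seed = mix_seed(seed, 31))
  list(image = img, mask = lay$mask, shapes = lay$shapes, style = style)
}

#' Generate a synthetic dataset on disk
#'
#' Writes PNG tiles, 16-bit TIFF instance masks, binary PNG masks, per-tile
#' JSON layout metadata, and a split manifest CSV. Slides (styles) are cycled
#' across images so inter-slide stain variation is present; splits are
#' assigned by slide so no slide straddles a split. Fully reproducible per
#' seed.
#'
#' @param n_images number of tiles.
#' @param canvas length-2 (H, W).
#' @param out_dir output directory.
#' @param n_styles number of distinct slide styles.
#' @param n_nuclei Poisson rate of nuclei per tile.
#' @param split train/val/test fractions, summing to 1.
#' @param seed RNG seed.
#' @return manifest data.frame (invisibly also written as `manifest.csv`).
#' @export
generate_dataset <- function(n_images, canvas, out_dir, n_styles = 5,
                             n_nuclei = 30, split = c(0.8, 0, 0.2),
                             seed = 1L) {
  stopifnot(n_images >= 1, abs(sum(split) - 1) < 1e-9)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  styles <- lapply(seq_len(n_styles), function(s)
    slide_style(seed = mix_seed(seed, s)))
  slide_of <- rep(seq_len(n_styles), length.out = n_images)
  split_names <- c("train", "val", "test")
  cnt <- round(split * n_styles)
  cnt[1] <- n_styles - sum(cnt[-1])
  if (any(cnt < 0)) stop("split fractions incompatible with n_styles")
  slide_split <- rep(split_names, times = cnt)
  rows <- list()
  for (i in seq_len(n_images)) {
    s <- synth_sample(canvas, n_nuclei, seed = mix_seed(seed, 1000 + i),
                      style = styles[[slide_of[i]]])
    stem <- sprintf("tile%04d", i)
    write_image(s$image, file.path(out_dir, paste0(stem, ".png")))
    write_mask(s$mask, file.path(out_dir, paste0(stem, "_instances.tif")))
    write_mask((s$mask > 0) * 1L, file.path(out_dir, paste0(stem, "_binary.png")))
    jsonlite::write_json(list(n_nuclei = max(s$mask), shapes = s$shapes),
                         file.path(out_dir, paste0(stem, ".json")),
                         dataframe = "rows", digits = NA)
    rows[[i]] <- data.frame(
      image = paste0(stem, ".png"), mask = paste0(stem, "_instances.tif"),
      slide = slide_of[i], split = slide_split[slide_of[i]])
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Generate a synthetic tile set in memory
#'
#' Convenience for experiments and tests: `n` tiles across `n_styles` slide
#' styles (cycled), Poisson nucleus counts, fully seeded.
#'
#' @inheritParams generate_dataset
#' @param n number of tiles.
#' @return list with `images`, `masks` (instance), `styles` index per tile.
#' @export
synth_tiles <- function(n, canvas = c(128, 128), n_nuclei = 8, n_styles = 5,
                        seed = 1L) {
  styles <- lapply(seq_len(n_styles), function(s)
    slide_style(seed = mix_seed(seed, s)))
  slide_of <- rep(seq_len(n_styles), length.out = n)
  out <- lapply(seq_len(n), function(i)
    synth_sample(canvas, n_nuclei, seed = mix_seed(seed, 1000 + i),
                 style = styles[[slide_of[i]]]))
  list(images = lapply(out, `[[`, "image"),
       masks = lapply(out, `[[`, "mask"),
       styles = slide_of)
}
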