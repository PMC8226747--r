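#' Deterministic offline augmentation
#'
#' Training sets are expanded before training (offline), not per epoch. The
#' recipes are fully deterministic: a grid crop, horizontal flips, vertical
#' flips of everything so far, then fixed-offset translate/crop/resize passes
#' (some followed by horizontal flips). Every geometric transform is applied
#' identically to the image and its mask (bilinear interpolation for images,
#' nearest-neighbor for masks, so no interpolated labels appear).
#'
#' @name augmentation
NULL

resize_bilinear <- function(image, h, w) {
  out <- cpp_resize_bilinear(array(as.numeric(image), dim = dim(image)),
                             as.integer(h), as.integer(w))
  out <- round(out)
  out[out < 0] <- 0; out[out > 255] <- 255
  storage.mode(out) <- "integer"
  out
}

resize_nearest <- function(mask, h, w) {
  m <- mask
  storage.mode(m) <- "integer"
  cpp_resize_nearest(m, as.integer(h), as.integer(w))
}

#' Flip an image or mask horizontally / vertically
#' @param x H x W matrix or H x W x C array.
#' @return flipped object of the same shape.
#' @export
flip_h <- function(x) {
  if (is.matrix(x)) x[, ncol(x):1]
  else x[, dim(x)[2]:1, , drop = FALSE]
}

#' @rdname flip_h
#' @export
flip_v <- function(x) {
  if (is.matrix(x)) x[nrow(x):1, ]
  else x[dim(x)[1]:1, , , drop = FALSE]
}

#' Grid crop an image/mask pair
#'
#' Crops of `size` x `size` at all top-left offsets `0, stride, 2*stride, ...`
#' that fit fully inside the image, in row-major offset order.
#'
#' @param image H x W x 3 array.
#' @param mask H x W matrix (or `NULL`).
#' @param size crop side length (pixels).
#' @param stride offset step (pixels).
#' @return list of `list(image, mask)` crops.
#' @export
grid_crop <- function(image, mask, size, stride) {
  d <- dim(image)
  if (size > d[1] || size > d[2]) stop("crop size exceeds image size")
  offs_r <- seq(0L, d[1] - size, by = stride)
  offs_c <- seq(0L, d[2] - size, by = stride)
  out <- list()
  for (r in offs_r) for (cc in offs_c) {
    out[[length(out) + 1L]] <- list(
      image = image[r + seq_len(size), cc + seq_len(size), , drop = FALSE],
      mask = if (is.null(mask)) NULL else
        mask[r + seq_len(size), cc + seq_len(size)])
  }
  out
}

#' Translate, crop the valid region, and resize back
#'
#' Shifts content by `(dx, dy)` (x = columns, y = rows; positive = right/
#' down), keeps the region that stays on canvas, and rescales it back to
#' `out_size` (bilinear for the image, nearest for the mask).
#'
#' @param image H x W x 3 array.
#' @param mask H x W matrix or `NULL`.
#' @param dx,dy integer offsets; `|dx|, |dy|` must be smaller than the size.
#' @param out_size output side length; default the input size.
#' @return `list(image, mask)`.
#' @export
translate_crop_resize <- function(image, mask, dx, dy, out_size = NULL) {
  d <- dim(image)
  if (abs(dx) >= d[2] || abs(dy) >= d[1]) stop("shift must be smaller than the image")
  rows <- if (dy >= 0) seq_len(d[1] - dy) else seq(1 - dy, d[1])
  cols <- if (dx >= 0) seq_len(d[2] - dx) else seq(1 - dx, d[2])
  if (is.null(out_size)) out_size <- c(d[1], d[2]) else
    out_size <- rep(out_size, length.out = 2)
  img <- image[rows, cols, , drop = FALSE]
  msk <- if (is.null(mask)) NULL else mask[rows, cols]
  list(image = resize_bilinear(img, out_size[1], out_size[2]),
       mask = if (is.null(msk)) NULL else
         resize_nearest(msk, out_size[1], out_size[2]))
}

#' Preset augmentation recipes
#'
#' `preset_tcga()`: for 1000x1000 tiles — 500x500 grid crop at stride 500
#' (4 per tile), horizontal flips, vertical flips of all so far, then three
#' translate/crop/resize passes at offsets (+10,+10), (-5,-5) with horizontal
#' flips, and (+5,+5) with horizontal flips. 30 tiles yield 2880 images.
#'
#' `preset_tnbc()`: for 512x512 tiles — 502x502 grid crop at stride 10
#' (4 per tile) resized back to 512, horizontal flips, vertical flips of all
#' so far, then two translate/crop/resize passes at (+5,+5) and (-5,-5).
#' 43 tiles yield 2064 images.
#'
#' @return an `aug_recipe` list.
#' @export
preset_tcga <- function() {
  structure(list(name = "tcga", crop_size = 500L, crop_stride = 500L,
                 resize_to = NULL,
                 tcr_steps = list(list(dx = 10, dy = 10, hflip = FALSE),
                                  list(dx = -5, dy = -5, hflip = TRUE),
                                  list(dx = 5, dy = 5, hflip = TRUE))),
            class = "aug_recipe")
}

#' @rdname preset_tcga
#' @export
preset_tnbc <- function() {
  structure(list(name = "tnbc", crop_size = 502L, crop_stride = 10L,
                 resize_to = 512L,
                 tcr_steps = list(list(dx = 5, dy = 5, hflip = FALSE),
                                  list(dx = -5, dy = -5, hflip = FALSE))),
            class = "aug_recipe")
}

augment_one <- function(image, mask, recipe) {
  crops <- grid_crop(image, mask, recipe$crop_size, recipe$crop_stride)
  if (!is.null(recipe$resize_to)) {
    crops <- lapply(crops, function(p) list(
      image = resize_bilinear(p$image, recipe$resize_to, recipe$resize_to),
      mask = if (is.null(p$mask)) NULL else
        resize_nearest(p$mask, recipe$resize_to, recipe$resize_to)))
  }
  tag <- function(set, chain) lapply(seq_along(set), function(i) {
    s <- set[[i]]; s$chain <- sprintf("%s%d", chain, i); s
  })
  s0 <- tag(crops, "crop")
  hf <- function(p, suffix) list(image = flip_h(p$image),
                                 mask = if (is.null(p$mask)) NULL else flip_h(p$mask),
                                 chain = paste0(p$chain, suffix))
  vf <- function(p) list(image = flip_v(p$image),
                         mask = if (is.null(p$mask)) NULL else flip_v(p$mask),
                         chain = paste0(p$chain, "+vflip"))
  s1 <- lapply(s0, hf, suffix = "+hflip")
  s2 <- lapply(c(s0, s1), vf)
  base <- c(s0, s1, s2)
  tcr_out <- list()
  for (st in recipe$tcr_steps) {
    tr <- lapply(base, function(p) {
      q <- translate_crop_resize(p$image, p$mask, st$dx, st$dy)
      q$chain <- sprintf("%s+tcr(%+d,%+d)", p$chain, st$dx, st$dy)
      q
    })
    if (isTRUE(st$hflip)) tr <- c(tr, lapply(tr, hf, suffix = "+hflip"))
    tcr_out <- c(tcr_out, tr)
  }
  list(outputs = c(base, tcr_out),
       ledger = c(crops = length(s0), hflip = length(s1), vflip = length(s2),
                  translate_crop_resize = length(tcr_out)))
}

#' Run an augmentation recipe over a set of image/mask pairs
#'
#' Processes one source image at a time (bounded memory). With `out_dir` the
#' outputs are written as PNG images and 16-bit TIFF masks with a provenance
#' manifest CSV; otherwise the outputs are returned in memory unless
#' `keep = FALSE`, in which case only the ledger and manifest are returned.
#'
#' @param images list of H x W x 3 arrays.
#' @param masks list of H x W matrices (or `NULL` for images only).
#' @param recipe an `aug_recipe` from [preset_tcga()] / [preset_tnbc()].
#' @param out_dir optional output directory.
#' @param keep keep outputs in memory (ignored when `out_dir` is given).
#' @return list with `ledger` (per-step counts incl. `total`), `manifest`
#'   (data.frame source / chain / file), and (if kept) `images`, `masks`.
#' @export
run_recipe <- function(images, masks = NULL, recipe, out_dir = NULL,
                       keep = is.null(out_dir)) {
  stopifnot(inherits(recipe, "aug_recipe"))
  if (is.null(masks)) masks <- vector("list", length(images))
  ledger <- c(crops = 0, hflip = 0, vflip = 0, translate_crop_resize = 0)
  manifest <- list()
  out_images <- list(); out_masks <- list()
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(images)) {
    a <- augment_one(images[[i]], masks[[i]], recipe)
    ledger <- ledger + a$ledger
    for (j in seq_along(a$outputs)) {
      o <- a$outputs[[j]]
      fname <- sprintf("src%03d_%04d", i, j)
      manifest[[length(manifest) + 1L]] <-
        data.frame(source = i, chain = o$chain, file = fname)
      if (!is.null(out_dir)) {
        write_image(o$image, file.path(out_dir, paste0(fname, ".png")))
        if (!is.null(o$mask))
          write_mask(o$mask, file.path(out_dir, paste0(fname, "_mask.tif")))
      } else if (keep) {
        out_images[[length(out_images) + 1L]] <- o$image
        out_masks[[length(out_masks) + 1L]] <- o$mask
      }
    }
  }
  ledger <- c(ledger, total = sum(ledger))
  res <- list(ledger = ledger, manifest = do.call(rbind, manifest))
  if (keep && is.null(out_dir)) {
    res$images <- out_images
    res$masks <- out_masks
  }
  res
}
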