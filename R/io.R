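#' Image and mask file I/O
#'
#' Conventions used throughout the package: pixels are addressed as
#' (row, col), 1-based inside R; annotation files use x = column, y = row,
#' 0-based pixel centers. RGB images are 8-bit PNG/TIFF; instance masks are
#' 16-bit single-channel TIFF/PNG (lossless label round trip); binary masks
#' are 8-bit 0/255 PNG mapped to `{0, 1}` on read.
#'
#' @name nucseg-io
NULL

#' Read an RGB image
#' @param path PNG or TIFF file.
#' @return H x W x 3 integer array in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", path))
  if (length(dim(a)) == 2L) stop("expected an RGB image, got 1 channel: ", path)
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  out <- round(a * 255)
  storage.mode(out) <- "integer"
  out
}

#' @rdname read_image
#' @param image H x W x 3 integer array.
#' @param path output file (.png or .tif).
#' @export
write_image <- function(image, path) {
  check_rgb(image)
  ext <- tolower(tools::file_ext(path))
  a <- image / 255
  switch(ext,
    png = png::writePNG(a, path),
    tif = , tiff = tiff::writeTIFF(a, path, bits.per.sample = 8L),
    stop("unsupported image format: ", path))
  invisible(path)
}

#' Read an instance or binary mask
#'
#' Single-channel 8-bit files with values only in \{0, 255\} are treated as
#' binary masks and mapped to `{0, 1}`; otherwise values are integer labels.
#'
#' @param path PNG or TIFF mask file.
#' @return H x W integer matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    stop("unsupported mask format: ", path))
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] == 1L) a <- a[, , 1] else
      stop("expected a single-channel mask, got ", dim(a)[3], " channels: ", path)
  }
  if (ext == "png") {
    v <- round(a * 255)
    if (all(v %in% c(0, 255))) v <- v / 255 else {
      # 16-bit png: readPNG scales by 65535
      v <- round(a * 65535)
      if (max(v) > 65535) stop("unsupported bit depth: ", path)
    }
    a <- v
  }
  out <- matrix(as.integer(round(a)), nrow = nrow(a))
  out
}

#' @rdname read_mask
#' @param mask H x W integer matrix of labels (<= 65535).
#' @export
write_mask <- function(mask, path) {
  check_instance_mask(mask)
  if (max(mask) > 65535) stop("labels exceed 16-bit range")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = {
      if (max(mask) <= 1) png::writePNG(matrix(mask / 1, nrow = nrow(mask)), path)
      else png::writePNG(mask / 65535, path)
    },
    tif = , tiff = tiff::writeTIFF(matrix(mask / 65535, nrow = nrow(mask)),
                                   path, bits.per.sample = 16L),
    stop("unsupported mask format: ", path))
  invisible(path)
}

#' Parse Aperio-style XML polygon annotations
#'
#' Extracts every `Annotation/Regions/Region/Vertices/Vertex` polygon as a
#' matrix of (x, y) vertex coordinates in pixel units.
#'
#' @param path XML file.
#' @return list of N x 2 numeric matrices (columns x, y).
#' @export
read_polygon_annotation <- function(path) {
  doc <- xml2::read_xml(path)
  regions <- xml2::xml_find_all(doc, ".//Region")
  lapply(regions, function(r) {
    vs <- xml2::xml_find_all(r, ".//Vertex")
    cbind(x = as.numeric(xml2::xml_attr(vs, "X")),
          y = as.numeric(xml2::xml_attr(vs, "Y")))
  })
}

#' Rasterize polygons to an instance mask
#'
#' Even-odd rule with the pixel-center-inside convention: pixel (row, col)
#' (0-based) is filled when its center point (x = col, y = row) lies inside
#' the polygon. Later polygons overwrite earlier ones; polygons with fewer
#' than 3 vertices are skipped with a warning.
#'
#' @param polygons list of N x 2 matrices (columns x, y), pixel units,
#'   0-based.
#' @param shape length-2 (H, W).
#' @return H x W integer instance mask.
#' @export
polygons_to_instance_mask <- function(polygons, shape) {
  H <- shape[1]; W <- shape[2]
  mask <- matrix(0L, H, W)
  lab <- 0L
  for (poly in polygons) {
    if (is.null(dim(poly)) || nrow(poly) < 3L) {
      warning("skipping polygon with fewer than 3 vertices")
      next
    }
    lab <- lab + 1L
    xs <- poly[, 1]; ys <- poly[, 2]
    n <- length(xs)
    x2 <- xs[c(2:n, 1)]; y2 <- ys[c(2:n, 1)]
    for (row in 0:(H - 1)) {
      # half-open rule on y avoids double-counting vertices
      lower <- pmin(ys, y2); upper <- pmax(ys, y2)
      cross <- which(lower <= row & row < upper & ys != y2)
      if (length(cross) == 0L) next
      xc <- xs[cross] + (row - ys[cross]) * (x2[cross] - xs[cross]) /
        (y2[cross] - ys[cross])
      xc <- sort(xc)
      for (k in seq(1, length(xc) - 1, by = 2)) {
        c0 <- ceiling(xc[k]); c1 <- ceiling(xc[k + 1]) - 1
        c0 <- max(c0, 0); c1 <- min(c1, W - 1)
        if (c1 >= c0) mask[row + 1L, (c0:c1) + 1L] <- lab
      }
    }
  }
  mask
}

#' Read / split a dataset manifest
#'
#' A manifest is a CSV with columns `image`, `mask`, `slide` (patient/slide
#' id), `split`. Splitting by slide id guarantees no slide appears in two
#' splits (the leave-one-patient-out contract).
#'
#' @param path manifest CSV.
#' @param base_dir directory that paths are relative to; defaults to the
#'   manifest's directory.
#' @param check verify the referenced files exist.
#' @return data.frame with absolute `image`/`mask` paths.
#' @export
read_manifest <- function(path, base_dir = dirname(path), check = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "mask", "slide", "split")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  df$image <- file.path(base_dir, df$image)
  df$mask <- file.path(base_dir, df$mask)
  if (check) {
    missing <- c(df$image[!file.exists(df$image)], df$mask[!file.exists(df$mask)])
    if (length(missing) > 0)
      stop("manifest references missing files: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  df
}

#' Leave-one-slide-out folds
#' @param manifest data.frame from [read_manifest()].
#' @return list of lists with `train` and `test` row indices per held-out slide.
#' @export
loo_folds <- function(manifest) {
  slides <- unique(manifest$slide)
  lapply(slides, function(s)
    list(slide = s,
         train = which(manifest$slide != s),
         test = which(manifest$slide == s)))
}
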