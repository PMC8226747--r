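#' Macenko stain normalization
#'
#' H&E tiles vary in color because of staining protocol, scanner, and slide
#' age. Stain mixtures are linear in optical-density (OD) space (Beer-Lambert
#' law), so a tile can be decomposed into per-stain concentration maps against
#' its own two stain vectors and re-rendered against a fixed reference basis,
#' giving every tile a standard appearance. The stain vectors are estimated
#' from the extreme angles of the tissue OD point cloud projected onto its
#' top-2 singular plane.
#'
#' @name stain-normalization
NULL

#' Canonical H&E reference stain basis
#'
#' The widely used reference values for hematoxylin and eosin OD vectors and
#' the reference maximum (99th percentile) concentrations. These are a
#' conventional choice, overridable in [norm_config()].
#'
#' @return A `stain_basis` object with attribute-free unit rows.
#' @export
reference_he_basis <- function() {
  stain_basis(
    hematoxylin = c(0.5626, 0.7201, 0.4062),
    eosin       = c(0.2159, 0.8012, 0.5581)
  )
}

#' Construct a stain basis
#'
#' Two unit-norm, componentwise non-negative OD vectors, one per stain.
#' Negative components (possible from raw SVD directions) are clamped to zero
#' before normalization.
#'
#' @param hematoxylin,eosin length-3 numeric OD vectors.
#' @return A `stain_basis`: list with unit vectors `hematoxylin` and `eosin`.
#' @export
stain_basis <- function(hematoxylin, eosin) {
  fix <- function(v, what) {
    v <- as.numeric(v)
    if (length(v) != 3L || !all(is.finite(v)))
      stop(what, " must be a finite length-3 vector")
    v[v < 0] <- 0
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop(what, " vector is numerically zero")
    v / n
  }
  h <- fix(hematoxylin, "hematoxylin")
  e <- fix(eosin, "eosin")
  cr <- abs(sum(h * e))
  if (cr > 1 - 1e-9) stop("degenerate stain plane: stain vectors are parallel")
  structure(list(hematoxylin = h, eosin = e), class = "stain_basis")
}

#' Stain-normalization configuration
#'
#' @param i0 transmitted (background) light intensity; the OD of a pixel with
#'   intensity `i0` is zero. Default 240.
#' @param beta OD threshold: pixels with any channel OD at or below `beta` are
#'   excluded from stain-vector estimation (white background and faint pixels).
#'   Default 0.15.
#' @param alpha robust angle percentile (percent): the stain vectors are the
#'   `alpha` and `100 - alpha` percentile angles of the projected OD cloud.
#'   Default 1.
#' @param conc_percentile percentile used as the "maximum" stain concentration
#'   when rescaling to the reference. Default 99.
#' @param beta_rule `"any"` (drop pixel if any channel OD <= beta, default) or
#'   `"all"` (drop only if all channels are faint).
#' @param reference_basis a [stain_basis()]; defaults to [reference_he_basis()].
#' @param reference_max_conc length-2 numeric, target `conc_percentile`
#'   concentrations for (hematoxylin, eosin).
#' @return A `norm_config` list.
#' @export
norm_config <- function(i0 = 240, beta = 0.15, alpha = 1, conc_percentile = 99,
                        beta_rule = c("any", "all"),
                        reference_basis = reference_he_basis(),
                        reference_max_conc = c(1.9705, 1.0308)) {
  beta_rule <- match.arg(beta_rule)
  stopifnot(i0 > 0, i0 <= 255, beta > 0, alpha > 0, alpha < 50,
            conc_percentile > 50, conc_percentile <= 100,
            inherits(reference_basis, "stain_basis"),
            length(reference_max_conc) == 2L, all(reference_max_conc > 0))
  structure(list(i0 = i0, beta = beta, alpha = alpha,
                 conc_percentile = conc_percentile, beta_rule = beta_rule,
                 reference_basis = reference_basis,
                 reference_max_conc = as.numeric(reference_max_conc)),
            class = "norm_config")
}

check_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array")
  if (anyNA(image) || any(image < 0) || any(image > 255))
    stop("pixel values must lie in [0, 255]")
  if (any(image != round(image)))
    stop("pixel values must be integers (8-bit intensities)")
  invisible(image)
}

#' RGB to optical density
#'
#' `od = log10(i0 / max(I, 1))` per channel: darker pixels have larger OD.
#' Zero intensities are clamped to 1 so the OD stays finite.
#'
#' @param image H x W x 3 integer array in `[0, 255]`.
#' @param i0 transmitted light intensity (> 0).
#' @return H x W x 3 non-negative OD array.
#' @export
rgb_to_od <- function(image, i0 = 240) {
  check_rgb(image)
  stopifnot(i0 > 0)
  od <- log10(i0 / pmax(image, 1))
  od[od < 0] <- 0  # pixels brighter than i0 carry no stain
  od
}

#' Optical density to RGB
#'
#' Inverse of [rgb_to_od()]: `I = round(i0 * 10^(-od))`, clipped to `[0, 255]`.
#'
#' @param od H x W x 3 non-negative OD array.
#' @param i0 transmitted light intensity.
#' @return H x W x 3 integer array.
#' @export
od_to_rgb <- function(od, i0 = 240) {
  if (anyNA(od) || any(od < 0)) stop("od must be non-negative and finite")
  out <- round(i0 * 10^(-od))
  out[out > 255] <- 255
  out[out < 0] <- 0
  storage.mode(out) <- "integer"
  out
}

# OD pixels (N x 3) passing the beta filter
od_foreground <- function(odm, beta, beta_rule) {
  keep <- if (beta_rule == "any") {
    odm[, 1] > beta & odm[, 2] > beta & odm[, 3] > beta
  } else {
    odm[, 1] > beta | odm[, 2] > beta | odm[, 3] > beta
  }
  odm[keep, , drop = FALSE]
}

#' Estimate the two-stain basis of an image
#'
#' Converts to OD, drops faint pixels (`beta` filter), takes the top-2
#' singular plane of the OD cloud, and returns the unit OD vectors at the
#' robust extreme angles (`alpha` / `100 - alpha` percentiles) of the
#' projected pixels. The vector with the larger red-channel OD component is
#' hematoxylin (hematoxylin absorbs red most); ties break on the green
#' component.
#'
#' @param image H x W x 3 integer array.
#' @param config a [norm_config()].
#' @param min_pixels minimum number of tissue pixels required.
#' @return A [stain_basis()].
#' @export
estimate_stain_basis <- function(image, config = norm_config(),
                                 min_pixels = 100) {
  od <- rgb_to_od(image, config$i0)
  odm <- matrix(od, ncol = 3L)
  fg <- od_foreground(odm, config$beta, config$beta_rule)
  if (nrow(fg) < min_pixels)
    stop("insufficient tissue: only ", nrow(fg),
         " pixels exceed the OD threshold")
  sv <- svd(fg, nu = 0, nv = 3)
  # 8-bit quantization alone leaves a second singular value below ~0.5% of
  # the first; a genuine two-stain cloud sits well above that floor
  if (sv$d[2] < 0.01 * sv$d[1])
    stop("degenerate stain plane: OD cloud is effectively one-dimensional")
  V <- sv$v[, 1:2, drop = FALSE]
  # orient the plane so projections fall in a consistent half-space
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  if (sum(V[, 2]) < 0) V[, 2] <- -V[, 2]
  proj <- fg %*% V
  ang <- atan2(proj[, 2], proj[, 1])
  lo <- stats::quantile(ang, config$alpha / 100, names = FALSE)
  hi <- stats::quantile(ang, 1 - config$alpha / 100, names = FALSE)
  v1 <- as.numeric(V %*% c(cos(lo), sin(lo)))
  v2 <- as.numeric(V %*% c(cos(hi), sin(hi)))
  # hematoxylin = larger red OD component; tie-break on green
  first_is_h <- if (abs(v1[1] - v2[1]) > 1e-12) v1[1] > v2[1] else v1[2] > v2[2]
  if (first_is_h) stain_basis(v1, v2) else stain_basis(v2, v1)
}

#' Per-pixel stain concentrations
#'
#' Least-squares decomposition of each pixel's OD onto the two basis vectors;
#' negative solutions are clipped to zero.
#'
#' @param od H x W x 3 OD array.
#' @param basis a [stain_basis()].
#' @param max_condition error if the basis condition number exceeds this.
#' @return H x W x 2 non-negative concentration array
#'   (`[,,1]` hematoxylin, `[,,2]` eosin).
#' @export
compute_concentrations <- function(od, basis, max_condition = 1e6) {
  stopifnot(inherits(basis, "stain_basis"))
  M <- cbind(basis$hematoxylin, basis$eosin)  # 3 x 2
  sv <- svd(M)
  if (sv$d[2] < 1e-12 || sv$d[1] / sv$d[2] > max_condition)
    stop("stain basis is near-parallel (condition number too large)")
  pinv <- sv$v %*% diag(1 / sv$d) %*% t(sv$u)  # 2 x 3
  d <- dim(od)
  conc <- matrix(od, ncol = 3L) %*% t(pinv)
  conc[conc < 0] <- 0
  array(conc, dim = c(d[1], d[2], 2L))
}

#' Normalize an image to the reference stain appearance
#'
#' Estimates the image's own stain basis, computes concentrations, rescales
#' each stain so its `conc_percentile` concentration matches
#' `reference_max_conc`, and re-renders through the reference basis.
#'
#' @inheritParams estimate_stain_basis
#' @return H x W x 3 integer array, same shape as the input.
#' @export
normalize_image <- function(image, config = norm_config()) {
  basis <- estimate_stain_basis(image, config)
  od <- rgb_to_od(image, config$i0)
  conc <- compute_concentrations(od, basis)
  d <- dim(conc)
  cm <- matrix(conc, ncol = 2L)
  for (k in 1:2) {
    mx <- stats::quantile(cm[, k], config$conc_percentile / 100, names = FALSE)
    if (mx > 1e-8) cm[, k] <- cm[, k] * (config$reference_max_conc[k] / mx)
  }
  ref <- rbind(config$reference_basis$hematoxylin,
               config$reference_basis$eosin)  # 2 x 3
  od_new <- cm %*% ref
  od_to_rgb(array(od_new, dim = c(d[1], d[2], 3L)), config$i0)
}

#' Per-image intensity histograms and summary
#'
#' 256-bin histogram of the rounded per-pixel channel mean (luminance) for
#' each image, with per-image mean and variance, for pre/post normalization
#' comparisons.
#'
#' @param images list of H x W x 3 integer arrays.
#' @return list with `histograms` (list of length-256 integer vectors,
#'   bins 0..255), `mean`, `variance` (numeric vectors).
#' @export
histogram_report <- function(images) {
  if (!is.list(images) || length(images) == 0L)
    stop("images must be a non-empty list")
  hs <- lapply(images, function(im) {
    check_rgb(im)
    g <- round((im[, , 1] + im[, , 2] + im[, , 3]) / 3)
    tabulate(as.integer(g) + 1L, nbins = 256L)
  })
  list(histograms = hs,
       mean = vapply(images, mean, numeric(1)),
       variance = vapply(images, function(im) stats::var(as.numeric(im)),
                         numeric(1)))
}
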