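#' Instance-mask utilities and segmentation metrics
#'
#' Evaluation is two-level: object-level precision/recall/F1 with a true
#' positive defined by 50% overlap between a ground-truth nucleus and its
#' matched prediction, and pixel-level Dice coefficient and aggregated
#' Jaccard index (AJI). The AJI matches each ground-truth instance to the
#' prediction maximizing the Jaccard index (each prediction usable once),
#' sums matched intersections over matched unions, and adds every unmatched
#' predicted pixel to the denominator, so both over- and under-segmentation
#' lower it.
#'
#' @name segmentation-metrics
NULL

check_instance_mask <- function(m, what = "mask") {
  if (!is.matrix(m)) stop(what, " must be an integer matrix")
  if (anyNA(m) || any(m < 0)) stop(what, " labels must be non-negative")
  invisible(m)
}

#' Label connected components of a binary mask
#'
#' 8-connected components, labeled 1..K in raster order (row-major scan) of
#' each component's first pixel.
#'
#' @param binary H x W matrix; nonzero = foreground.
#' @return H x W integer matrix of instance labels (0 = background).
#' @export
label_components <- function(binary) {
  if (!is.matrix(binary)) stop("binary must be a matrix")
  m <- matrix(as.integer(binary != 0), nrow = nrow(binary))
  cpp_label_components(m)
}

# joint pixel-count table of two label masks, rows gt 0..K, cols pred 0..L
label_contingency <- function(gt, pred) {
  K <- max(gt, 0L); L <- max(pred, 0L)
  idx <- as.integer(gt) + as.integer(K + 1L) * as.integer(pred)
  cnt <- tabulate(idx + 1L, nbins = (K + 1L) * (L + 1L))
  matrix(cnt, nrow = K + 1L, ncol = L + 1L)
}

#' Match predicted to ground-truth instances
#'
#' Greedy one-to-one matching by descending pairwise overlap score. Under the
#' default `"iou"` rule a pair is a true positive iff its intersection-over-
#' union is at least `threshold`; the `"gt-coverage"` rule instead requires
#' the matched prediction to cover at least `threshold` of the ground-truth
#' instance. Ties break by (gt id, pred id).
#'
#' @param gt,pred instance masks (integer matrices, 0 = background).
#' @param threshold overlap threshold for a true positive (default 0.5).
#' @param rule `"iou"` (default) or `"gt-coverage"`.
#' @return list with counts `TP`, `FP`, `FN` and `pairs`
#'   (data.frame `gt`, `pred`, `score` for matched pairs).
#' @export
match_objects <- function(gt, pred, threshold = 0.5,
                          rule = c("iou", "gt-coverage")) {
  rule <- match.arg(rule)
  check_instance_mask(gt, "gt"); check_instance_mask(pred, "pred")
  if (!identical(dim(gt), dim(pred))) stop("mask shape mismatch")
  K <- max(gt, 0L); L <- max(pred, 0L)
  pairs <- data.frame(gt = integer(), pred = integer(), score = numeric())
  if (K > 0L && L > 0L) {
    ct <- label_contingency(gt, pred)
    gsz <- rowSums(ct)[-1]; psz <- colSums(ct)[-1]
    inter <- ct[-1, -1, drop = FALSE]
    score <- if (rule == "iou") {
      inter / (outer(gsz, psz, `+`) - inter)
    } else {
      inter / gsz
    }
    cand <- which(score > 0, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(-score[cand], cand[, 1], cand[, 2])
      used_g <- logical(K); used_p <- logical(L)
      for (r in ord) {
        gi <- cand[r, 1]; pj <- cand[r, 2]
        if (used_g[gi] || used_p[pj]) next
        if (score[gi, pj] >= threshold) {
          used_g[gi] <- TRUE; used_p[pj] <- TRUE
          pairs <- rbind(pairs, data.frame(gt = gi, pred = pj,
                                           score = score[gi, pj]))
        }
      }
    }
  }
  TP <- nrow(pairs)
  list(TP = TP, FP = L - TP, FN = K - TP, pairs = pairs)
}

#' Object-level precision, recall, and F1
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2TP/(2TP+FP+FN)`; zero denominators yield 0.
#'
#' @param match result of [match_objects()] (or any list with TP, FP, FN).
#' @return list `precision`, `recall`, `f1`.
#' @export
object_prf <- function(match) {
  TP <- match$TP; FP <- match$FP; FN <- match$FN
  safe <- function(num, den) if (den > 0) num / den else 0
  list(precision = safe(TP, TP + FP),
       recall = safe(TP, TP + FN),
       f1 = safe(2 * TP, 2 * TP + FP + FN))
}

#' Pixel-level Dice coefficient
#'
#' `2|G.S| / (|G| + |S|)` on binary foregrounds; two empty masks score 1.
#'
#' @param gt,pred binary masks (or instance masks; any nonzero pixel is
#'   foreground).
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred))) stop("mask shape mismatch")
  g <- gt != 0; s <- pred != 0
  denom <- sum(g) + sum(s)
  if (denom == 0) return(1)
  2 * sum(g & s) / denom
}

#' Aggregated Jaccard index
#'
#' For each ground-truth instance (in id order) the unused predicted instance
#' maximizing the Jaccard index is consumed; matched intersections are summed
#' over matched unions plus all pixels of unmatched predictions. Ground-truth
#' instances with no overlapping prediction contribute their full size to the
#' denominator. Jaccard ties break toward the lower prediction id.
#'
#' @param gt,pred instance masks (integer matrices, 0 = background).
#' @return scalar in `[0, 1]`.
#' @export
aji <- function(gt, pred) {
  check_instance_mask(gt, "gt"); check_instance_mask(pred, "pred")
  if (!identical(dim(gt), dim(pred))) stop("mask shape mismatch")
  K <- max(gt, 0L); L <- max(pred, 0L)
  if (K == 0L && L == 0L) return(1)
  if (K == 0L) return(0)
  ct <- label_contingency(gt, pred)
  gsz <- rowSums(ct)[-1]
  psz <- if (L > 0) colSums(ct)[-1] else numeric(0)
  inter <- if (L > 0) ct[-1, -1, drop = FALSE] else
    matrix(0, nrow = K, ncol = 0)
  used <- logical(L)
  num <- 0; den <- 0
  for (i in seq_len(K)) {
    if (L > 0L && any(!used)) {
      js <- which(!used)
      jac <- inter[i, js] / (gsz[i] + psz[js] - inter[i, js])
      best <- js[which.max(jac)]  # which.max takes the first (lowest id) tie
      if (inter[i, best] > 0) {
        num <- num + inter[i, best]
        den <- den + gsz[i] + psz[best] - inter[i, best]
        used[best] <- TRUE
        next
      }
    }
    den <- den + gsz[i]  # unmatched ground truth
  }
  den <- den + sum(psz[!used])
  if (den == 0) return(1)
  num / den
}

#' Full metric report for one mask pair
#'
#' @inheritParams match_objects
#' @return list `precision`, `recall`, `f1`, `dice`, `aji`, `TP`, `FP`, `FN`.
#' @export
metric_report <- function(gt, pred, threshold = 0.5,
                          rule = c("iou", "gt-coverage")) {
  m <- match_objects(gt, pred, threshold, rule)
  prf <- object_prf(m)
  c(prf, list(dice = dice(gt, pred), aji = aji(gt, pred),
              TP = m$TP, FP = m$FP, FN = m$FN))
}

#' Evaluate directories of paired masks
#'
#' Pairs ground-truth and predicted mask files by base name, computes the
#' metric report per image, and appends a macro average. Instance masks are
#' 16-bit single-channel PNG/TIFF; binary masks (8-bit 0/255) are labeled by
#' [label_components()] first.
#'
#' @param gt_dir,pred_dir directories of mask files.
#' @param threshold,rule forwarded to [match_objects()].
#' @param out_csv,out_json optional report paths.
#' @return data.frame, one row per image plus a `macro_average` row.
#' @export
evaluate_masks <- function(gt_dir, pred_dir, threshold = 0.5,
                           rule = c("iou", "gt-coverage"),
                           out_csv = NULL, out_json = NULL) {
  rule <- match.arg(rule)
  gt_files <- sort(list.files(gt_dir, "\\.(png|tif|tiff)$", ignore.case = TRUE))
  pred_files <- sort(list.files(pred_dir, "\\.(png|tif|tiff)$", ignore.case = TRUE))
  key <- function(f) tools::file_path_sans_ext(f)
  miss <- c(setdiff(key(gt_files), key(pred_files)),
            setdiff(key(pred_files), key(gt_files)))
  if (length(miss) > 0)
    stop("unpaired mask files: ", paste(miss, collapse = ", "))
  rows <- lapply(key(gt_files), function(k) {
    g <- read_mask(file.path(gt_dir, gt_files[key(gt_files) == k]))
    p <- read_mask(file.path(pred_dir, pred_files[key(pred_files) == k]))
    if (max(g) <= 1) g <- label_components(g)
    if (max(p) <= 1) p <- label_components(p)
    r <- metric_report(g, p, threshold, rule)
    data.frame(image = k, precision = r$precision, recall = r$recall,
               f1 = r$f1, dice = r$dice, aji = r$aji)
  })
  df <- do.call(rbind, rows)
  avg <- data.frame(image = "macro_average",
                    precision = mean(df$precision), recall = mean(df$recall),
                    f1 = mean(df$f1), dice = mean(df$dice), aji = mean(df$aji))
  out <- rbind(df, avg)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  if (!is.null(out_json))
    jsonlite::write_json(out, out_json, dataframe = "rows", digits = NA)
  out
}
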