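# Evaluation layer: smoothed Sorensen-Dice and Jaccard overlap, the
# structural similarity index, the image-level false positive rate on
# soil-only images, pixel-pooled ROC curves, and per-method aggregation
# into report rows.

check_masks <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
}

#' Sorensen-Dice similarity coefficient
#'
#' `(2|A ∩ B| + smooth) / (|A| + |B| + smooth)`. The additive
#' smoothing constant (default 1) makes the coefficient defined for
#' empty masks: an all-zero prediction against a b-pixel mask scores
#' `1/(b+1)` rather than 0, and empty-vs-empty scores 1 (perfect
#' agreement on an image with no roots). `smooth = 0` gives the bare
#' coefficient.
#'
#' @param pred,truth same-shape binary masks.
#' @param smooth smoothing constant >= 0.
#' @return Value in \[0,1\].
#' @export
dsc <- function(pred, truth, smooth = 1) {
  check_masks(pred, truth)
  if (smooth < 0) stop("smooth must be >= 0")
  inter <- sum(pred * truth)
  denom <- sum(pred) + sum(truth) + smooth
  if (denom == 0) stop("undefined metric: empty masks with smooth = 0")
  (2 * inter + smooth) / denom
}

#' Jaccard index / intersection over union
#'
#' `(|A ∩ B| + smooth) / (|A ∪ B| + smooth)`; same smoothing
#' convention as [dsc()]. For zero-intersection predictions the smoothed
#' IoU equals the smoothed DSC.
#'
#' @inheritParams dsc
#' @return Value in \[0,1\].
#' @export
iou <- function(pred, truth, smooth = 1) {
  check_masks(pred, truth)
  if (smooth < 0) stop("smooth must be >= 0")
  inter <- sum(pred * truth)
  uni <- sum(pred) + sum(truth) - inter
  if (uni + smooth == 0) stop("undefined metric: empty masks with smooth = 0")
  (inter + smooth) / (uni + smooth)
}

#' Structural similarity index
#'
#' Mean over local Gaussian windows of the luminance x contrast x
#' structure product with the standard stabilising constants
#' `(k1*range)^2` and `(k2*range)^2`. Masks and score maps are compared
#' as real-valued images with dynamic range 1; local statistics use an
#' 11-tap Gaussian window (sigma 1.5) with reflective boundaries, and
#' the global index is the mean of the per-window map.
#'
#' @param x,y same-shape single-channel images.
#' @param window_size odd window width in px.
#' @param sigma Gaussian window sigma in px.
#' @param k1,k2 stabilising constants.
#' @param dynamic_range value range of the inputs.
#' @return The mean SSIM, clipped to \[0,1\] in the aggregate reports
#'   (the raw value in \[-1,1\] is returned here).
#' @export
ssim_index <- function(x, y, window_size = 11, sigma = 1.5,
                       k1 = 0.01, k2 = 0.03, dynamic_range = 1) {
  if (!identical(dim(x), dim(y))) stop("image shapes differ")
  r <- (window_size - 1) %/% 2
  k <- gaussian_kernel(sigma, r)
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  mx <- conv_sep(x, k); my <- conv_sep(y, k)
  vx <- conv_sep(x * x, k) - mx^2
  vy <- conv_sep(y * y, k) - my^2
  cxy <- conv_sep(x * y, k) - mx * my
  ssim_map <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(ssim_map)
}

#' Image-level false positive rate on soil-only images
#'
#' FP/(FP+TN) over the soil-only images (those with an empty true
#' mask): an image counts as a false positive as soon as its prediction
#' contains at least `min_area` root pixels (default 1, the strictest
#' reading of "falsely classified as containing roots"). Methods that
#' predict no roots on any image at all do not meaningfully participate
#' and are flagged excluded rather than scored 0.
#'
#' @param pred_masks list of predicted binary masks.
#' @param true_masks list of ground-truth binary masks (same order).
#' @param min_area minimum predicted root pixels for an image to count
#'   as containing roots.
#' @return A list with `fpr` (rate in \[0,1\], or `NA` when excluded),
#'   `excluded` (logical), `fp`, `tn`, `n_soil_only`.
#' @export
image_level_fpr <- function(pred_masks, true_masks, min_area = 1) {
  stopifnot(length(pred_masks) == length(true_masks))
  soil <- vapply(true_masks, function(m) sum(m) == 0, TRUE)
  if (!any(soil)) stop("undefined rate: no soil-only images in the set")
  pred_any <- vapply(pred_masks, function(m) sum(m) >= min_area, TRUE)
  if (!any(vapply(pred_masks, function(m) sum(m) > 0, TRUE))) {
    return(list(fpr = NA_real_, excluded = TRUE, fp = 0L,
                tn = sum(soil), n_soil_only = sum(soil)))
  }
  fp <- sum(pred_any & soil)
  tn <- sum(!pred_any & soil)
  list(fpr = fp / (fp + tn), excluded = FALSE, fp = fp, tn = tn,
       n_soil_only = sum(soil))
}

#' Pixel-pooled ROC curve
#'
#' Pools every pixel of every image, then for each of `n_thresholds`
#' evenly spaced thresholds computes the true and false positive rates
#' of `score >= t`. A leading threshold above the score range anchors
#' the curve at (0,0); `t = 0` anchors it at (1,1). AUC is computed by
#' the trapezoid rule. Constant (dummy) scores produce the diagonal,
#' AUC 0.5.
#'
#' @param score_maps list of score matrices in \[0,1\] (or a single
#'   matrix).
#' @param true_masks list of binary masks (or a single matrix).
#' @param n_thresholds number of evenly spaced thresholds in \[0,1\].
#' @return A list of class `rs_roc` with a `curve` tibble (threshold,
#'   tpr, fpr) and `auc`.
#' @export
roc_curve <- function(score_maps, true_masks, n_thresholds = 256) {
  if (is.matrix(score_maps)) score_maps <- list(score_maps)
  if (is.matrix(true_masks)) true_masks <- list(true_masks)
  scores <- unlist(lapply(score_maps, as.numeric))
  truth <- unlist(lapply(true_masks, as.numeric))
  stopifnot(length(scores) == length(truth))
  n_pos <- sum(truth); n_neg <- length(truth) - n_pos
  if (n_pos == 0 || n_neg == 0) {
    stop("undefined curve: pooled ground truth contains a single class")
  }
  th <- seq(1, 0, length.out = n_thresholds)
  # bin counts per threshold interval, then cumulative tails
  pos_bins <- tabulate(findInterval(scores[truth == 1], rev(th)) + 1L,
                       nbins = n_thresholds + 1L)
  neg_bins <- tabulate(findInterval(scores[truth == 0], rev(th)) + 1L,
                       nbins = n_thresholds + 1L)
  # findInterval(x, rev(th)) = number of thresholds <= x; score >= th[i]
  # pools all bins with at least (n_thresholds - i + 1) thresholds <= x
  pos_tail <- rev(cumsum(rev(pos_bins)))
  neg_tail <- rev(cumsum(rev(neg_bins)))
  tpr <- c(0, pos_tail[seq(n_thresholds + 1L, 2L)] / n_pos)
  fpr <- c(0, neg_tail[seq(n_thresholds + 1L, 2L)] / n_neg)
  curve <- tibble::tibble(threshold = c(Inf, th), tpr = tpr, fpr = fpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc, n_pixels = length(scores)),
            class = "rs_roc")
}

#' @export
print.rs_roc <- function(x, ...) {
  cat(sprintf("<rs_roc> %d thresholds, %d pooled pixels, AUC = %.4f\n",
              nrow(x$curve) - 1, x$n_pixels, x$auc))
  invisible(x)
}

binarize <- function(scores, threshold) (scores >= threshold) * 1

#' Evaluate one method's score maps against a bundle
#'
#' Binarises each score map at `threshold`, averages per-image SSIM
#' (computed between the binarised prediction and the true mask), DSC
#' and IoU (smoothed), computes the image-level FPR over the soil-only
#' images (or flags it excluded for never-predicting methods), and
#' retains the pooled ROC when the scores are non-binary.
#'
#' @param score_maps list of score matrices, one per bundle row.
#' @param bundle the evaluated `rs_bundle`.
#' @param method method tag for the report row.
#' @param threshold binarisation level (default 0.5).
#' @param smooth smoothing constant for DSC/IoU.
#' @return A one-row tibble (class `rs_metrics_row`): `method`,
#'   `mean_ssim`, `mean_dsc`, `mean_iou`, `fpr`, `fpr_excluded`,
#'   `n_images`, `n_soil_only`, and a `roc` list-column (`NULL` when the
#'   scores were already binary or truth is single-class).
#' @export
evaluate_method <- function(score_maps, bundle, method = "method",
                            threshold = 0.5, smooth = 1) {
  n <- nrow(bundle)
  stopifnot(length(score_maps) == n)
  masks <- bundle$mask
  preds <- lapply(score_maps, binarize, threshold = threshold)
  per_ssim <- mapply(function(p, t) min(max(ssim_index(p, t), 0), 1),
                     preds, masks)
  per_dsc <- mapply(dsc, preds, masks, MoreArgs = list(smooth = smooth))
  per_iou <- mapply(iou, preds, masks, MoreArgs = list(smooth = smooth))
  fp <- if (any(bundle$soil_only)) {
    image_level_fpr(preds, masks)
  } else list(fpr = NA_real_, excluded = NA, n_soil_only = 0L)
  non_binary <- any(vapply(score_maps, function(s) any(s > 0 & s < 1), TRUE))
  roc <- NULL
  total_pos <- sum(vapply(masks, sum, 0))
  if (non_binary && total_pos > 0) roc <- roc_curve(score_maps, masks)
  out <- tibble::tibble(
    method = method,
    mean_ssim = mean(per_ssim), mean_dsc = mean(per_dsc),
    mean_iou = mean(per_iou),
    fpr = fp$fpr, fpr_excluded = fp$excluded,
    n_images = n, n_soil_only = sum(bundle$soil_only),
    roc = list(roc)
  )
  class(out) <- c("rs_metrics_row", class(out))
  out
}
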