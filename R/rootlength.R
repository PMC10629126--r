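# Root length from binary masks: morphological thinning to a
# one-pixel-wide skeleton, pixel-count x mm/px length estimation, and
# the predicted-vs-labelled regression report.

#' Skeletonise a binary mask
#'
#' Zhang-Suen iterative thinning: pixels are peeled from alternating
#' sub-iterations until no removable pixel remains, leaving a
#' 1-pixel-wide, 8-connected medial skeleton that preserves the mask's
#' topology. The skeleton is always a subset of the mask; an empty mask
#' yields an empty skeleton.
#'
#' @param mask H x W matrix of 0/1.
#' @return Binary skeleton matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  h <- nrow(img); w <- ncol(img)
  if (sum(img) == 0) return(img)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbours P2..P9 clockwise from north
      p2 <- shift(img, -1, 0); p3 <- shift(img, -1, 1)
      p4 <- shift(img, 0, 1);  p5 <- shift(img, 1, 1)
      p6 <- shift(img, 1, 0);  p7 <- shift(img, 1, -1)
      p8 <- shift(img, 0, -1); p9 <- shift(img, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      # 0->1 transitions in the cyclic sequence P2..P9,P2
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (phase == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- img == 1L & bsum >= 2 & bsum <= 6 & a == 1 & cond
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

#' Total root length of a mask in mm
#'
#' Skeletonises the mask and multiplies the skeleton pixel count by the
#' mm-per-pixel relation (the plain pixel-count estimator). The opt-in
#' `diagonal_weighted` variant instead sums skeleton steps, weighting
#' 8-connected diagonal links by sqrt(2); the default pixel count
#' under-measures diagonally oriented roots by up to that factor, an
#' orientation bias that is documented rather than silently corrected.
#'
#' @param mask binary mask.
#' @param pixel_scale mm per pixel (> 0).
#' @param diagonal_weighted use the sqrt(2)-weighted step estimator.
#' @return Length in mm (>= 0).
#' @export
length_mm <- function(mask, pixel_scale, diagonal_weighted = FALSE) {
  if (pixel_scale <= 0) stop("pixel_scale must be > 0")
  sk <- skeletonize(mask)
  if (!diagonal_weighted) return(sum(sk) * pixel_scale)
  h <- nrow(sk); w <- ncol(sk)
  # count each axial / diagonal link between skeleton pixels once
  ax <- sum(sk[-h, ] * sk[-1, ]) + sum(sk[, -w] * sk[, -1])
  dg <- sum(sk[-h, -w] * sk[-1, -1]) + sum(sk[-h, -1] * sk[-1, -w])
  n_links <- ax + sqrt(2) * dg
  iso <- sum(sk) > 0 && ax + dg == 0
  (if (iso) sum(sk) else n_links) * pixel_scale
}

#' Per-image length records for a set of predictions
#'
#' @param pred_masks list of predicted binary masks.
#' @param bundle the evaluated `rs_bundle`; labelled lengths are taken
#'   from the ground-truth mask skeleton at each pair's pixel scale.
#' @return A tibble with `image_id`, `labelled_mm`, `predicted_mm`,
#'   `pixel_scale`.
#' @export
length_records <- function(pred_masks, bundle) {
  stopifnot(length(pred_masks) == nrow(bundle))
  tibble::tibble(
    image_id = bundle$id,
    labelled_mm = vapply(seq_len(nrow(bundle)), function(i) {
      length_mm(bundle$mask[[i]], bundle$pixel_scale[i])
    }, 0),
    predicted_mm = vapply(seq_len(nrow(bundle)), function(i) {
      length_mm(pred_masks[[i]], bundle$pixel_scale[i])
    }, 0),
    pixel_scale = bundle$pixel_scale
  )
}

#' Regress predicted on labelled root length
#'
#' Ordinary least squares of predicted length on labelled length with
#' an intercept; reports slope, intercept, R-squared and t-based 95%
#' confidence intervals.
#'
#' @param records tibble with `labelled_mm` and `predicted_mm` (n >= 3).
#' @return A list of class `rs_regression` with `slope`, `intercept`,
#'   `r2`, `ci95_slope`, `ci95_intercept`, `n` and the underlying `lm`
#'   fit.
#' @export
length_regression <- function(records) {
  if (nrow(records) < 3) stop("need at least 3 length records")
  if (sd(records$labelled_mm) < 1e-12) {
    stop("degenerate regression: labelled lengths have zero variance")
  }
  fit <- lm(predicted_mm ~ labelled_mm, data = records)
  ci <- confint(fit, level = 0.95)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r2 = summary(fit)$r.squared,
    ci95_slope = unname(ci["labelled_mm", ]),
    ci95_intercept = unname(ci["(Intercept)", ]),
    n = nrow(records), fit = fit, records = records
  ), class = "rs_regression")
}

#' @export
print.rs_regression <- function(x, ...) {
  cat(sprintf(
    "<rs_regression> n = %d\n  predicted = %.4f * labelled + %.4f,  R^2 = %.4f\n  95%% CI slope [%.4f, %.4f], intercept [%.4f, %.4f]\n",
    x$n, x$slope, x$intercept, x$r2, x$ci95_slope[1], x$ci95_slope[2],
    x$ci95_intercept[1], x$ci95_intercept[2]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a length regression
#'
#' @param x an `rs_regression`.
#' @param ... unused.
#' @return One row per model term with estimate, standard error,
#'   statistic, p-value and the 95% confidence bounds.
#' @export
tidy.rs_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4],
    conf.low = c(x$ci95_intercept[1], x$ci95_slope[1]),
    conf.high = c(x$ci95_intercept[2], x$ci95_slope[2])
  )
}

#' One-row summary of a length regression
#'
#' @param x an `rs_regression`.
#' @param ... unused.
#' @return A tibble with `r.squared`, `sigma`, `slope`, `intercept`,
#'   `nobs`.
#' @export
glance.rs_regression <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, sigma = summary(x$fit)$sigma,
                 slope = x$slope, intercept = x$intercept, nobs = x$n)
}
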