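# Non-neural segmenters: the majority-class dummy baseline, Frangi
# vesselness on a bilateral-filtered green-minus-blue channel, locally
# adaptive thresholding tuned by validation Dice, and a pixel-wise
# colour SVM.

new_scoremap <- function(scores, method, threshold = 0.5) {
  structure(list(scores = scores, method = method, threshold = threshold),
            class = "rs_scoremap")
}

#' @export
print.rs_scoremap <- function(x, ...) {
  cat(sprintf("<rs_scoremap %s> %dx%d, range [%.3f, %.3f], threshold %.2f\n",
              x$method, nrow(x$scores), ncol(x$scores), min(x$scores),
              max(x$scores), x$threshold))
  invisible(x)
}

#' Dummy (majority-class) segmenter
#'
#' Predicts the most frequent class everywhere -- the zero label, i.e.
#' "no roots". Serves as the baseline that any useful method must beat;
#' its smoothed DSC equals 1/(|B|+1) on an image with a B-pixel mask and
#' 1 on soil-only images.
#'
#' @param image any H x W x 3 array or H x W matrix.
#' @return An `rs_scoremap` of all-zero scores.
#' @export
dummy_segment <- function(image) {
  d <- dim(image)
  new_scoremap(matrix(0, d[1], d[2]), "dummy")
}

#' Edge-preserving bilateral filter
#'
#' Classic bilateral smoothing: each output pixel is a normalised
#' average of its spatial neighbours, weighted by a spatial Gaussian and
#' a range Gaussian on intensity difference, so soil texture is smoothed
#' while root edges survive.
#'
#' @param channel H x W matrix in \[0,1\].
#' @param sigma_spatial spatial Gaussian sigma in px.
#' @param sigma_range range Gaussian sigma on the \[0,1\] intensity
#'   scale.
#' @return Filtered matrix, same shape.
#' @export
bilateral_filter <- function(channel, sigma_spatial = 3, sigma_range = 0.1) {
  r <- ceiling(2 * sigma_spatial)
  h <- nrow(channel); w <- ncol(channel)
  mp <- pad_reflect(channel, r)
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  for (dy in -r:r) {
    for (dx in -r:r) {
      ws <- exp(-(dy^2 + dx^2) / (2 * sigma_spatial^2))
      shifted <- mp[(r + dy) + seq_len(h), (r + dx) + seq_len(w)]
      wr <- exp(-(shifted - channel)^2 / (2 * sigma_range^2))
      num <- num + ws * wr * shifted
      den <- den + ws * wr
    }
  }
  num / den
}

#' Pre-process an RGB image for vesselness filtering
#'
#' Applies an edge-preserving bilateral filter to each channel, takes
#' the green-minus-blue difference (roots image warmer than wet soil,
#' so G-B carries root contrast while suppressing blue-ish background),
#' and rescales the result to \[0,1\]. A constant-colour image maps to a
#' constant output.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param sigma_spatial,sigma_range bilateral filter parameters.
#' @return H x W matrix in \[0,1\].
#' @export
frangi_preprocess <- function(image, sigma_spatial = 3, sigma_range = 0.1) {
  g <- bilateral_filter(image[, , 2], sigma_spatial, sigma_range)
  b <- bilateral_filter(image[, , 3], sigma_spatial, sigma_range)
  d <- g - b
  rng <- range(d)
  if (rng[2] - rng[1] < 1e-12) return(matrix(0, nrow(d), ncol(d)))
  (d - rng[1]) / (rng[2] - rng[1])
}

#' Frangi vesselness parameters
#'
#' @param scales smoothing scales sigma in px (non-empty, > 0).
#' @param beta blobness weight (> 0).
#' @param c structureness weight; `NA` selects it adaptively per image
#'   and scale as half the maximum Hessian Frobenius norm.
#' @param polarity `"bright"` for bright ridges on dark background,
#'   `"dark"` for the opposite.
#' @return A list of class `rs_frangi_params`.
#' @export
frangi_params <- function(scales = c(1, 2, 3, 4), beta = 0.5, c = NA,
                          polarity = c("bright", "dark")) {
  if (length(scales) == 0 || any(scales <= 0)) stop("scales must be positive")
  if (beta <= 0) stop("beta must be > 0")
  polarity <- match.arg(polarity)
  structure(list(scales = scales, beta = beta, c = c, polarity = polarity),
            class = "rs_frangi_params")
}

# Scale-normalised Hessian of a single-channel image at scale sigma,
# via separable Gaussian-derivative convolutions with reflective
# boundaries; each component is multiplied by sigma^2.
hessian_at_scale <- function(channel, sigma) {
  k <- gaussian_deriv_kernels(sigma)
  list(
    rr = sigma^2 * conv_sep(channel, k$g2, k$g0),
    cc = sigma^2 * conv_sep(channel, k$g0, k$g2),
    rc = sigma^2 * conv_sep(channel, k$g1, k$g1)
  )
}

#' Frangi vesselness filter
#'
#' Per-pixel tubularity response: at each scale the Hessian eigenvalues
#' `|l1| <= |l2|` give the blobness ratio `Rb = |l1|/|l2|` and
#' structureness `S = sqrt(l1^2 + l2^2)`, combined as
#' `V = exp(-Rb^2 / 2 beta^2) * (1 - exp(-S^2 / 2 c^2))`, zeroed where
#' the sign of `l2` contradicts the requested polarity (bright ridges
#' need `l2 < 0`). The final response is the per-pixel maximum over
#' scales; a constant image gives an all-zero response.
#'
#' @param channel H x W matrix (single-channel image).
#' @param params an [frangi_params()].
#' @return An `rs_scoremap` with values in \[0,1\].
#' @export
frangi_vesselness <- function(channel, params = frangi_params()) {
  h <- nrow(channel); w <- ncol(channel)
  out <- matrix(0, h, w)
  for (sigma in params$scales) {
    hs <- hessian_at_scale(channel, sigma)
    # eigenvalues of the symmetric 2x2 Hessian
    tr <- hs$rr + hs$cc
    disc <- sqrt(pmax((hs$rr - hs$cc)^2 + 4 * hs$rc^2, 0))
    e1 <- (tr + disc) / 2
    e2 <- (tr - disc) / 2
    # order by absolute value: |l1| <= |l2|
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    s2 <- l1^2 + l2^2
    if (is.na(params$c)) {
      smax <- sqrt(max(s2))
      if (smax < 1e-10) next      # flat image: no structure at this scale
      cval <- smax / 2
    } else {
      cval <- params$c
    }
    if (cval <= 0) cval <- 1e-10
    rb2 <- ifelse(abs(l2) > 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * params$beta^2)) * (1 - exp(-s2 / (2 * cval^2)))
    ok <- if (params$polarity == "bright") l2 < 0 else l2 > 0
    v[!ok] <- 0
    out <- pmax(out, v)
  }
  new_scoremap(out, "frangi")
}

#' Segment an image with Frangi vesselness
#'
#' Convenience wrapper: [frangi_preprocess()] then
#' [frangi_vesselness()].
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param params an [frangi_params()].
#' @return An `rs_scoremap`.
#' @export
frangi_segment <- function(image, params = frangi_params()) {
  frangi_vesselness(frangi_preprocess(image), params)
}

#' Adaptive thresholding parameters
#'
#' @param block_size odd local window width in px, >= 3.
#' @param offset constant the local mean must be exceeded by, on the
#'   \[0,1\] intensity scale.
#' @param weighting `"gaussian"` or `"uniform"` window weights.
#' @return A list of class `rs_adaptive_params`.
#' @export
adaptive_params <- function(block_size = 31, offset = 0.02,
                            weighting = c("gaussian", "uniform")) {
  if (block_size %% 2 == 0 || block_size < 3) {
    stop("invalid params: block_size must be odd and >= 3")
  }
  structure(list(block_size = block_size, offset = offset,
                 weighting = match.arg(weighting)),
            class = "rs_adaptive_params")
}

#' Locally adaptive thresholding
#'
#' Converts the image to greyscale luminance and marks a pixel as root
#' iff its value exceeds the local (uniform or Gaussian-weighted) mean
#' over a `block_size` window by more than `offset`. Local illumination
#' is thereby divided out, which a single global threshold cannot do.
#' The Gaussian window sigma follows the usual
#' `0.3 * ((block_size - 1) / 2 - 1) + 0.8` convention.
#'
#' @param image H x W x 3 array or greyscale matrix.
#' @param params an [adaptive_params()].
#' @return A binary-valued `rs_scoremap`.
#' @export
adaptive_threshold <- function(image, params = adaptive_params()) {
  grey <- rgb_to_grey(image)
  b <- params$block_size
  k <- if (params$weighting == "uniform") {
    rep(1 / b, b)
  } else {
    gaussian_kernel(0.3 * ((b - 1) / 2 - 1) + 0.8, (b - 1) %/% 2)
  }
  local_mean <- conv_sep(grey, k)
  new_scoremap((grey > local_mean + params$offset) * 1, "adaptive")
}

#' Tune adaptive thresholding on a validation bundle
#'
#' Exhaustively evaluates a parameter grid and returns the combination
#' with the highest mean validation DSC (smoothed); ties are broken by
#' smaller block size, then smaller offset. Deterministic.
#'
#' @param grid data frame with columns `block_size`, `offset` and
#'   optionally `weighting`.
#' @param val validation `rs_bundle`.
#' @param smooth DSC smoothing constant.
#' @return The winning [adaptive_params()], with the achieved mean DSC
#'   attached as attribute `"val_dsc"`.
#' @export
tune_adaptive <- function(grid, val, smooth = 1) {
  if (is.null(grid) || nrow(grid) == 0) stop("empty parameter grid")
  if (is.null(grid$weighting)) grid$weighting <- "gaussian"
  greys <- lapply(val$image, rgb_to_grey)
  score <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- adaptive_params(grid$block_size[i], grid$offset[i], grid$weighting[i])
    d <- vapply(seq_along(greys), function(j) {
      pred <- adaptive_threshold(greys[[j]], p)$scores
      dsc(pred, val$mask[[j]], smooth = smooth)
    }, 0)
    score[i] <- mean(d)
  }
  ord <- order(-score, grid$block_size, grid$offset)
  best <- ord[1]
  out <- adaptive_params(grid$block_size[best], grid$offset[best],
                         grid$weighting[best])
  attr(out, "val_dsc") <- score[best]
  out
}

#' Default adaptive-threshold tuning grid
#'
#' @return A data frame covering block sizes 11 to 51 (step 4) and
#'   offsets 0 to 0.10 (step 0.01) with Gaussian weighting.
#' @export
adaptive_grid <- function() {
  expand.grid(block_size = seq(11, 51, by = 4),
              offset = seq(0, 0.10, by = 0.01),
              weighting = "gaussian", stringsAsFactors = FALSE)
}
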