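#' @importFrom stats rnorm runif rpois lm confint predict quantile sd
#' @importFrom utils head tail modifyList read.csv write.csv
NULL

# Images are numeric arrays: H x W x 3 (RGB) in [0,1]; masks are H x W
# matrices of 0/1. Row 1 is the top of the image; coordinates are
# row-major, 0-based in the tiling arithmetic, half-open tiles.

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Convert an RGB image to greyscale luminance
#'
#' Uses ITU-R 601 weights (0.299, 0.587, 0.114), the classic luma
#' transform used by most imaging toolboxes when a colour image is
#' reduced to "greyscale" without further qualification.
#'
#' @param image H x W x 3 array in \[0,1\], or an H x W matrix (returned
#'   unchanged).
#' @return H x W numeric matrix in \[0,1\].
#' @export
rgb_to_grey <- function(image) {
  if (is.matrix(image)) return(image)
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# Reflective (mirror, without repeating the edge sample) padding of a
# matrix by `p` pixels on every side. Falls back to edge replication
# when p >= dim.
pad_reflect <- function(m, p) {
  if (p == 0) return(m)
  h <- nrow(m); w <- ncol(m)
  ridx <- c(rev(seq_len(min(p, h - 1)) + 1L), seq_len(h),
            h - seq_len(min(p, h - 1)))
  ridx <- c(rep(ridx[1], p - min(p, h - 1)), ridx,
            rep(ridx[length(ridx)], p - min(p, h - 1)))
  cidx <- c(rev(seq_len(min(p, w - 1)) + 1L), seq_len(w),
            w - seq_len(min(p, w - 1)))
  cidx <- c(rep(cidx[1], p - min(p, w - 1)), cidx,
            rep(cidx[length(cidx)], p - min(p, w - 1)))
  m[ridx, cidx, drop = FALSE]
}

pad_reflect_rgb <- function(image, p) {
  out <- array(0, dim(image) + c(2 * p, 2 * p, 0))
  for (ch in seq_len(dim(image)[3])) out[, , ch] <- pad_reflect(image[, , ch], p)
  out
}

# Separable 2-D convolution (correlation; all kernels used here are
# symmetric or explicitly flipped by the caller) with reflective padding.
# `kr` runs down rows, `kc` across columns.
conv_sep <- function(m, kr, kc = kr) {
  pr <- (length(kr) - 1L) %/% 2L
  pc <- (length(kc) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  mp <- pad_reflect(m, max(pr, pc))
  off <- max(pr, pc)
  # rows pass
  acc <- matrix(0, h, ncol(mp))
  for (i in seq_along(kr)) {
    acc <- acc + kr[i] * mp[(off - pr + i - 1L) + seq_len(h), , drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (j in seq_along(kc)) {
    out <- out + kc[j] * acc[, (off - pc + j - 1L) + seq_len(w), drop = FALSE]
  }
  out
}

gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Unnormalised Gaussian and its exact first/second derivatives sampled on
# an integer grid; used by the vesselness Hessian.
gaussian_deriv_kernels <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  list(
    g0 = g / sum(g),
    g1 = -x / sigma^2 * g,
    g2 = g2 - mean(g2)      # DC-free: a constant image has zero response
  )
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  conv_sep(m, gaussian_kernel(sigma))
}

gaussian_blur_rgb <- function(image, sigma) {
  for (ch in seq_len(dim(image)[3])) image[, , ch] <- gaussian_blur(image[, , ch], sigma)
  image
}

# Deterministic per-item seed derivation: a splitmix-style integer hash
# of (master seed, index), folded into [0, 2^31 - 2] so it is always a
# valid R seed. Keeps parallel / incremental generation stable.
derive_seed <- function(master, index) {
  x <- (as.double(master) * 2654435761 + as.double(index) * 40503 + 12345) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

round_half_up <- function(x) floor(x + 0.5)
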