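# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, no separability tricks) so they
# share no code path with the implementations they check.

# -- fixtures ----------------------------------------------------------

# A flat-background pair with one straight horizontal tube of the given
# half-width (radius), drawn analytically.
tube_pair <- function(h = 64, w = 64, row = 32, radius = 2,
                      col_range = c(10, w - 10), bright = 0.4,
                      bg = 0.25, pixel_scale = 0.1, gradient = 0) {
  img <- array(bg, c(h, w, 3))
  if (gradient > 0) {
    g <- matrix(seq(0, gradient, length.out = w), h, w, byrow = TRUE)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + g
  }
  mask <- matrix(0, h, w)
  cols <- col_range[1]:col_range[2]
  for (r in seq_len(h)) {
    if (abs(r - row) <= radius) mask[r, cols] <- 1
  }
  for (ch in 1:3) img[, , ch] <- img[, , ch] + bright * c(1, 0.95, 0.75)[ch] * mask
  rs_pair(clamp01_t(img), mask, pixel_scale = pixel_scale, id = "tube",
          true_length_mm = (col_range[2] - col_range[1]) * pixel_scale)
}

clamp01_t <- function(x) pmin(pmax(x, 0), 1)

# Cheap large "stand-in" pair of stated dimensions (constant-ish image)
# for tiling count checks.
standin_pair <- function(h, w, id = "standin") {
  img <- array(0.5, c(h, w, 3))
  mask <- matrix(0, h, w)
  mask[seq(1, h, by = 97), seq(1, w, by = 101)] <- 1
  rs_pair(img, mask, pixel_scale = 0.01, id = id)
}

# Tiny bundle of flat pairs (cheap rows for split/mix bookkeeping).
tiny_bundle <- function(n, h = 8, domain = "default") {
  as_bundle(lapply(seq_len(n), function(i) {
    rs_pair(array(0.5, c(h, h, 3)), matrix(0, h, h), domain = domain,
            id = sprintf("%s_%03d", domain, i))
  }))
}

# -- oracles -----------------------------------------------------------

# Naive SSIM: per-pixel loop over Gaussian windows with reflective
# padding, no separable convolution.
naive_ssim <- function(x, y, window_size = 11, sigma = 1.5,
                       k1 = 0.01, k2 = 0.03) {
  r <- (window_size - 1) %/% 2
  kk <- outer(exp(-(-r:r)^2 / (2 * sigma^2)), exp(-(-r:r)^2 / (2 * sigma^2)))
  kk <- kk / sum(kk)
  h <- nrow(x); w <- ncol(x)
  reflect_idx <- function(i, n) {
    i[i < 1] <- 2 - i[i < 1]
    i[i > n] <- 2 * n - i[i > n]
    i
  }
  c1 <- k1^2; c2 <- k2^2
  total <- 0
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ri <- reflect_idx(i + (-r:r), h)
      ci <- reflect_idx(j + (-r:r), w)
      wx <- x[ri, ci]; wy <- y[ri, ci]
      mx <- sum(kk * wx); my <- sum(kk * wy)
      vx <- sum(kk * wx^2) - mx^2; vy <- sum(kk * wy^2) - my^2
      cxy <- sum(kk * wx * wy) - mx * my
      total <- total + ((2 * mx * my + c1) * (2 * cxy + c2)) /
        ((mx^2 + my^2 + c1) * (vx + vy + c2))
    }
  }
  total / (h * w)
}

# Naive adaptive threshold: per-pixel sliding window recomputation with
# reflective padding.
naive_adaptive <- function(grey, block_size, offset, weighting = "gaussian") {
  r <- (block_size - 1) %/% 2
  k1d <- if (weighting == "uniform") rep(1 / block_size, block_size) else {
    s <- 0.3 * ((block_size - 1) / 2 - 1) + 0.8
    kk <- exp(-(-r:r)^2 / (2 * s^2)); kk / sum(kk)
  }
  kk <- outer(k1d, k1d)
  h <- nrow(grey); w <- ncol(grey)
  reflect_idx <- function(i, n) {
    i[i < 1] <- 2 - i[i < 1]
    i[i > n] <- 2 * n - i[i > n]
    i
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ri <- reflect_idx(i + (-r:r), h)
      ci <- reflect_idx(j + (-r:r), w)
      lm <- sum(kk * grey[ri, ci])
      out[i, j] <- as.numeric(grey[i, j] > lm + offset)
    }
  }
  out
}

# Naive Frangi vesselness: full 2-D kernel convolution (explicit double
# loop over the kernel) for each Hessian component, then per-pixel
# eigen-decomposition via base eigen().
naive_vesselness <- function(channel, scales, beta = 0.5, cfix = NA,
                             polarity = "bright") {
  h <- nrow(channel); w <- ncol(channel)
  reflect_pad <- function(m, p) {
    ridx <- c(rev(seq_len(p) + 1), seq_len(nrow(m)), nrow(m) - seq_len(p))
    cidx <- c(rev(seq_len(p) + 1), seq_len(ncol(m)), ncol(m) - seq_len(p))
    m[ridx, cidx]
  }
  conv_full <- function(m, kern) {
    p <- (nrow(kern) - 1) / 2
    mp <- reflect_pad(m, p)
    out <- matrix(0, h, w)
    for (a in seq_len(nrow(kern))) {
      for (b in seq_len(ncol(kern))) {
        out <- out + kern[a, b] * mp[(a - 1) + seq_len(h), (b - 1) + seq_len(w)]
      }
    }
    out
  }
  best <- matrix(0, h, w)
  for (sigma in scales) {
    rad <- ceiling(4 * sigma)
    xs <- -rad:rad
    g0 <- exp(-xs^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
    g0n <- g0 / sum(g0)
    g1 <- -xs / sigma^2 * g0
    g2 <- (xs^2 - sigma^2) / sigma^4 * g0
    g2 <- g2 - mean(g2)
    hrr <- sigma^2 * conv_full(channel, outer(g2, g0n))
    hcc <- sigma^2 * conv_full(channel, outer(g0n, g2))
    hrc <- sigma^2 * conv_full(channel, outer(g1, g1))
    s2m <- matrix(0, h, w); vm <- matrix(0, h, w)
    l1m <- matrix(0, h, w); l2m <- matrix(0, h, w)
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        ev <- eigen(matrix(c(hrr[i, j], hrc[i, j], hrc[i, j], hcc[i, j]), 2),
                    symmetric = TRUE, only.values = TRUE)$values
        ev <- ev[order(abs(ev))]
        l1m[i, j] <- ev[1]; l2m[i, j] <- ev[2]
        s2m[i, j] <- sum(ev^2)
      }
    }
    cval <- if (is.na(cfix)) sqrt(max(s2m)) / 2 else cfix
    if (cval <= 0) cval <- 1e-10
    rb2 <- ifelse(abs(l2m) > 0, (l1m / l2m)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2m / (2 * cval^2)))
    v[if (polarity == "bright") l2m >= 0 else l2m <= 0] <- 0
    best <- pmax(best, v)
  }
  best
}
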