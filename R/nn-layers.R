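# Minimal convolutional-network engine used by the encoder-decoder
# segmentation models. Batched tensors are numeric arrays laid out as
# (H, W, B, C); convolutions are expressed as shifted-slice matrix
# products against BLAS so the whole engine is plain R. Every layer
# provides an explicit backward pass; gradients are verified against
# finite differences in the test suite.

# ---- convolution -----------------------------------------------------

# k x k convolution, zero-padded 'same'. W: (k, k, Cin, Cout), b: Cout.
# The im2col gather and scatter live in src/conv.cpp.
conv_fwd <- function(x, W, b) {
  list(out = conv_fwd_cpp(x, dim(x), W, dim(W), b), x = x)
}

conv_bwd <- function(dout, x, W) {
  conv_bwd_cpp(dout, x, dim(x), W, dim(W))
}

# ---- activations -----------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), x = x)
relu_bwd <- function(dout, x) dout * (x > 0)

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(out = y, y = y)
}
sigmoid_bwd <- function(dout, y) dout * y * (1 - y)

# ---- group normalisation ---------------------------------------------

# Channels are split into `groups`; mean/variance are taken over
# (H, W, channels-in-group) separately per image, so the layer behaves
# identically at any batch size -- the reason it replaces batch norm in
# annotation-scarce segmentation models.
gn_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; B <- d[3]; C <- d[4]
  gs <- C %/% groups
  stopifnot(gs * groups == C)
  m <- matrix(x, H * Wd, B * C)                     # col = (b, c), b fastest
  cm <- colMeans(m)
  cm2 <- colMeans(m^2)
  grp <- rep(seq_len(groups), each = gs)            # channel -> group
  gidx <- rep(grp, each = B) + groups * rep(seq_len(B) - 1, times = C)
  mu <- rowsum(cm, gidx)[, 1] / gs                  # per (b, g), g fastest
  m2 <- rowsum(cm2, gidx)[, 1] / gs
  var <- pmax(m2 - mu^2, 0)
  istd <- 1 / sqrt(var + eps)
  mu_col <- mu[gidx]; istd_col <- istd[gidx]
  hw <- H * Wd
  xhat <- (m - rep(mu_col, each = hw)) * rep(istd_col, each = hw)
  gamma_col <- rep(gamma, each = B)
  beta_col <- rep(beta, each = B)
  y <- xhat * rep(gamma_col, each = hw) + rep(beta_col, each = hw)
  list(out = array(y, d), xhat = xhat, istd = istd, gidx = gidx,
       gamma = gamma, dims = d, gs = gs)
}

gn_bwd <- function(dout, cache) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; B <- d[3]; C <- d[4]
  n <- H * Wd * cache$gs
  dm <- matrix(dout, H * Wd, B * C)
  gamma_col <- rep(cache$gamma, each = B)
  dgamma <- numeric(C); dbeta <- numeric(C)
  gx <- colSums(dm * cache$xhat)                     # per (b, c)
  gb <- colSums(dm)
  cidx <- rep(seq_len(C), each = B)
  dgamma <- rowsum(gx, cidx)[, 1]
  dbeta <- rowsum(gb, cidx)[, 1]
  hw <- H * Wd
  dxhat <- dm * rep(gamma_col, each = hw)
  sum_dxhat <- rowsum(colSums(dxhat), cache$gidx)[, 1]
  sum_dxhat_xhat <- rowsum(colSums(dxhat * cache$xhat), cache$gidx)[, 1]
  istd_col <- cache$istd[cache$gidx]
  t1 <- dxhat - rep(sum_dxhat[cache$gidx] / n, each = hw)
  t2 <- cache$xhat * rep(sum_dxhat_xhat[cache$gidx] / n, each = hw)
  dx <- (t1 - t2) * rep(istd_col, each = hw)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- pooling / unpooling / upsampling --------------------------------

pad_even <- function(x) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]
  H2 <- H + H %% 2; W2 <- Wd + Wd %% 2
  if (H2 == H && W2 == Wd) return(x)
  xp <- array(0, c(H2, W2, d[3], d[4]))
  xp[seq_len(H), seq_len(Wd), , ] <- x
  if (H2 > H) xp[H2, seq_len(Wd), , ] <- x[H, , , ]   # replicate edge
  if (W2 > Wd) xp[, W2, , ] <- xp[, Wd, , ]
  xp
}

# 2x2 max pooling, stride 2; records one-hot argmax masks (ties to the
# first window position) so segnet-style decoders can unpool.
pool_fwd <- function(x) {
  d0 <- dim(x)
  xp <- pad_even(x)
  d <- dim(xp); H <- d[1]; Wd <- d[2]
  ro <- seq(1, H, 2); re <- seq(2, H, 2)
  co <- seq(1, Wd, 2); ce <- seq(2, Wd, 2)
  s <- list(xp[ro, co, , , drop = FALSE], xp[re, co, , , drop = FALSE],
            xp[ro, ce, , , drop = FALSE], xp[re, ce, , , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  m1 <- s[[1]] == m
  m2 <- s[[2]] == m & !m1
  m3 <- s[[3]] == m & !m1 & !m2
  m4 <- s[[4]] == m & !m1 & !m2 & !m3
  list(out = m, masks = list(m1, m2, m3, m4), dims_in = d0, dims_pad = d)
}

pool_scatter <- function(values, cache) {
  d <- cache$dims_pad
  yp <- array(0, d)
  ro <- seq(1, d[1], 2); re <- seq(2, d[1], 2)
  co <- seq(1, d[2], 2); ce <- seq(2, d[2], 2)
  yp[ro, co, , ] <- values * cache$masks[[1]]
  yp[re, co, , ] <- yp[re, co, , , drop = FALSE] + values * cache$masks[[2]]
  yp[ro, ce, , ] <- yp[ro, ce, , , drop = FALSE] + values * cache$masks[[3]]
  yp[re, ce, , ] <- yp[re, ce, , , drop = FALSE] + values * cache$masks[[4]]
  d0 <- cache$dims_in
  # fold mass landing on replicated padding rows/cols back onto the edge
  if (d[1] > d0[1]) yp[d0[1], , , ] <- yp[d0[1], , , , drop = FALSE] +
      yp[d[1], , , , drop = FALSE]
  if (d[2] > d0[2]) yp[, d0[2], , ] <- yp[, d0[2], , , drop = FALSE] +
      yp[, d[2], , , drop = FALSE]
  yp[seq_len(d0[1]), seq_len(d0[2]), , , drop = FALSE]
}

pool_bwd <- function(dout, cache) pool_scatter(dout, cache)

# Max-unpooling (segnet decoder): place values at the argmax positions
# recorded by the matching pool layer.
unpool_fwd <- function(x, pool_cache) {
  list(out = pool_scatter(x, pool_cache), cache = pool_cache)
}

unpool_bwd <- function(dout, pool_cache) {
  d0 <- pool_cache$dims_in
  d <- pool_cache$dims_pad
  dp <- array(0, d)
  dp[seq_len(d0[1]), seq_len(d0[2]), , ] <- dout
  # adjoint of the edge fold in pool_scatter
  if (d[1] > d0[1]) dp[d[1], , , ] <- dp[d0[1], , , , drop = FALSE]
  if (d[2] > d0[2]) dp[, d[2], , ] <- dp[, d0[2], , , drop = FALSE]
  ro <- seq(1, d[1], 2); re <- seq(2, d[1], 2)
  co <- seq(1, d[2], 2); ce <- seq(2, d[2], 2)
  dp[ro, co, , , drop = FALSE] * pool_cache$masks[[1]] +
    dp[re, co, , , drop = FALSE] * pool_cache$masks[[2]] +
    dp[ro, ce, , , drop = FALSE] * pool_cache$masks[[3]] +
    dp[re, ce, , , drop = FALSE] * pool_cache$masks[[4]]
}

# Nearest-neighbour 2x upsampling, cropped to the target spatial shape
# (needed when the matching encoder level had odd extent).
upsample_fwd <- function(x, target_hw) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
         drop = FALSE]
  list(out = y[seq_len(target_hw[1]), seq_len(target_hw[2]), , , drop = FALSE],
       dims_in = d, target_hw = target_hw)
}

upsample_bwd <- function(dout, cache) {
  d <- cache$dims_in
  dy <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  dy[seq_len(cache$target_hw[1]), seq_len(cache$target_hw[2]), , ] <- dout
  ro <- seq(1, 2 * d[1], 2); re <- seq(2, 2 * d[1], 2)
  co <- seq(1, 2 * d[2], 2); ce <- seq(2, 2 * d[2], 2)
  dy[ro, co, , , drop = FALSE] + dy[re, co, , , drop = FALSE] +
    dy[ro, ce, , , drop = FALSE] + dy[re, ce, , , drop = FALSE]
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

split_c <- function(d, c1) {
  list(d[, , , seq_len(c1), drop = FALSE],
       d[, , , -seq_len(c1), drop = FALSE])
}
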