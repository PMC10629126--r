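# Encoder-decoder segmentation models built on the layer engine:
#  - segnet_style: VGG-ish blocks, max-pooling with recorded argmax
#    indices and index-based max-unpooling in the decoder, no skips;
#  - unet_gn_res: U-Net with group-norm residual blocks and an optional
#    two-channel (mask, negative-mask) head;
#  - backboned_unet: plain U-Net with a pluggable encoder (the "tiny"
#    encoder is the default; heavyweight pretrained backbones are out of
#    scope and would plug in behind the same interface).

#' Model specification
#'
#' @param family `"segnet_style"`, `"unet_gn_res"` or
#'   `"backboned_unet"`.
#' @param encoder encoder name for `backboned_unet` (only `"tiny"` is
#'   built in).
#' @param base_width channels at the first level; doubled at each
#'   deeper level.
#' @param depth number of resolution levels including the bottleneck
#'   (>= 1).
#' @param out_channels 1, or 2 for the (mask, negative-mask) head used
#'   by `unet_gn_res`.
#' @param seed parameter-initialisation seed.
#' @return A list of class `rs_model_spec`.
#' @export
model_spec <- function(family = c("backboned_unet", "unet_gn_res", "segnet_style"),
                       encoder = "tiny", base_width = 8, depth = 3,
                       out_channels = 1, seed = 1) {
  family <- match.arg(family)
  if (depth < 1) stop("depth must be >= 1")
  if (!out_channels %in% c(1, 2)) stop("out_channels must be 1 or 2")
  if (family == "backboned_unet" && encoder != "tiny") {
    stop("configuration error: unknown encoder '", encoder, "'")
  }
  structure(list(family = family, encoder = encoder,
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 out_channels = as.integer(out_channels),
                 final_activation = "sigmoid", seed = seed),
            class = "rs_model_spec")
}

gn_groups <- function(C) max(1L, C %/% 4L)

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

# Parameters of one conv block: two 3x3 conv + GN pairs, plus an
# optional 1x1 projection for residual blocks with a channel change.
init_block <- function(cin, cout, residual) {
  p <- list(
    W1 = he_init(3, cin, cout), b1 = numeric(cout),
    g1 = rep(1, cout), be1 = numeric(cout),
    W2 = he_init(3, cout, cout), b2 = numeric(cout),
    g2 = rep(1, cout), be2 = numeric(cout)
  )
  if (residual && cin != cout) {
    p$Wp <- he_init(1, cin, cout)
    p$bp <- numeric(cout)
  }
  p
}

block_fwd <- function(x, p, residual) {
  c1 <- conv_fwd(x, p$W1, p$b1)
  n1 <- gn_fwd(c1$out, p$g1, p$be1, gn_groups(length(p$b1)))
  r1 <- relu_fwd(n1$out)
  c2 <- conv_fwd(r1$out, p$W2, p$b2)
  n2 <- gn_fwd(c2$out, p$g2, p$be2, gn_groups(length(p$b2)))
  if (residual) {
    if (!is.null(p$Wp)) {
      pr <- conv_fwd(x, p$Wp, p$bp)
      shortcut <- pr$out
    } else {
      pr <- NULL
      shortcut <- x
    }
    r2 <- relu_fwd(n2$out + shortcut)
    cache <- list(c1 = c1, n1 = n1, r1 = r1, c2 = c2, n2 = n2, pr = pr,
                  r2 = r2, residual = TRUE)
  } else {
    r2 <- relu_fwd(n2$out)
    cache <- list(c1 = c1, n1 = n1, r1 = r1, c2 = c2, n2 = n2,
                  r2 = r2, residual = FALSE)
  }
  list(out = r2$out, cache = cache)
}

block_bwd <- function(dout, cache, p) {
  g <- list()
  dr2 <- relu_bwd(dout, cache$r2$x)
  dn2 <- gn_bwd(dr2, cache$n2)
  g$g2 <- dn2$dgamma; g$be2 <- dn2$dbeta
  dc2 <- conv_bwd(dn2$dx, cache$c2$x, p$W2)
  g$W2 <- dc2$dW; g$b2 <- dc2$db
  dr1 <- relu_bwd(dc2$dx, cache$r1$x)
  dn1 <- gn_bwd(dr1, cache$n1)
  g$g1 <- dn1$dgamma; g$be1 <- dn1$dbeta
  dc1 <- conv_bwd(dn1$dx, cache$c1$x, p$W1)
  g$W1 <- dc1$dW; g$b1 <- dc1$db
  dx <- dc1$dx
  if (cache$residual) {
    if (!is.null(cache$pr)) {
      dpr <- conv_bwd(dr2, cache$pr$x, p$Wp)
      g$Wp <- dpr$dW; g$bp <- dpr$db
      dx <- dx + dpr$dx
    } else {
      dx <- dx + dr2
    }
  }
  list(dx = dx, grads = g)
}

#' Build an encoder-decoder segmentation model
#'
#' Returns a trainable image-to-score-map model with sigmoid outputs in
#' \[0,1\]: skip connections for the U-Net families, pooling-index
#' unpooling for `segnet_style`, group-norm residual blocks for
#' `unet_gn_res`. A two-channel head predicts the mask and its negative
#' image.
#'
#' @param spec an [model_spec()].
#' @return An object of class `rs_nn_model`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "rs_model_spec"))
  residual <- spec$family == "unet_gn_res"
  widths <- spec$base_width * 2^(seq_len(spec$depth) - 1)
  with_seed(spec$seed, {
    enc <- vector("list", spec$depth)
    dec <- vector("list", max(spec$depth - 1, 0))
    for (i in seq_len(spec$depth)) {
      cin <- if (i == 1) 3L else widths[i - 1]
      enc[[i]] <- init_block(cin, widths[i], residual)
    }
    for (i in seq_len(max(spec$depth - 1, 0))) {
      # decoder level i receives upsampled widths[i+1] (+ skip widths[i]
      # for unet families) and emits widths[i]
      cin <- if (spec$family == "segnet_style") widths[i + 1] else
        widths[i + 1] + widths[i]
      dec[[i]] <- init_block(cin, widths[i], residual)
    }
    head <- list(W = he_init(1, widths[1], spec$out_channels),
                 b = numeric(spec$out_channels))
    structure(list(spec = spec,
                   params = list(enc = enc, dec = dec, head = head)),
              class = "rs_nn_model")
  })
}

#' @export
print.rs_nn_model <- function(x, ...) {
  cat(sprintf("<rs_nn_model %s> depth %d, width %d, %d output channel(s), %d parameters\n",
              x$spec$family, x$spec$depth, x$spec$base_width,
              x$spec$out_channels, n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model an `rs_nn_model`.
#' @return Integer parameter count; strictly increasing in
#'   `base_width`.
#' @export
n_parameters <- function(model) {
  sum(unlist(rapply(model$params, length, how = "unlist")))
}

# Recursive U-Net / SegNet forward from `level`; returns output and the
# cache tree consumed by nn_backward.
nn_fwd_level <- function(x, params, spec, level) {
  residual <- spec$family == "unet_gn_res"
  if (level == spec$depth) {
    b <- block_fwd(x, params$enc[[level]], residual)
    return(list(out = b$out, cache = list(block = b$cache, leaf = TRUE)))
  }
  b1 <- block_fwd(x, params$enc[[level]], residual)
  pl <- pool_fwd(b1$out)
  inner <- nn_fwd_level(pl$out, params, spec, level + 1)
  if (spec$family == "segnet_style") {
    # decoder block reduces channels at the coarse resolution, then the
    # recorded argmax indices scatter the features back up
    b2 <- block_fwd(inner$out, params$dec[[level]], residual)
    up <- unpool_fwd(b2$out, pl)
    out <- up$out
    ucache <- pl
  } else {
    hw <- dim(b1$out)[1:2]
    up <- upsample_fwd(inner$out, hw)
    merged <- concat_c(up$out, b1$out)
    b2 <- block_fwd(merged, params$dec[[level]], residual)
    out <- b2$out
    ucache <- up
  }
  list(out = out,
       cache = list(block = b1$cache, pool = pl, inner = inner$cache,
                    up = ucache, dec = b2$cache, leaf = FALSE,
                    skip_c = dim(inner$out)[4]))
}

nn_bwd_level <- function(dout, cache, params, spec, level, grads) {
  residual <- spec$family == "unet_gn_res"
  if (isTRUE(cache$leaf)) {
    bb <- block_bwd(dout, cache$block, params$enc[[level]])
    grads$enc[[level]] <- bb$grads
    return(list(dx = bb$dx, grads = grads))
  }
  if (spec$family == "segnet_style") {
    dup <- unpool_bwd(dout, cache$up)
    db2 <- block_bwd(dup, cache$dec, params$dec[[level]])
    grads$dec[[level]] <- db2$grads
    dinner <- db2$dx
    dskip <- NULL
  } else {
    db2 <- block_bwd(dout, cache$dec, params$dec[[level]])
    grads$dec[[level]] <- db2$grads
    parts <- split_c(db2$dx, cache$skip_c)
    dinner <- upsample_bwd(parts[[1]], cache$up)
    dskip <- parts[[2]]
  }
  inner <- nn_bwd_level(dinner, cache$inner, params, spec, level + 1, grads)
  grads <- inner$grads
  dpool <- pool_bwd(inner$dx, cache$pool)
  db1_in <- if (is.null(dskip)) dpool else dpool + dskip
  bb <- block_bwd(db1_in, cache$block, params$enc[[level]])
  grads$enc[[level]] <- bb$grads
  list(dx = bb$dx, grads = grads)
}

# Full forward pass on a batch tensor (H, W, B, 3); returns sigmoid
# scores (H, W, B, out_channels) plus the cache for nn_backward.
nn_forward <- function(model, x) {
  body <- nn_fwd_level(x, model$params, model$spec, 1L)
  hd <- conv_fwd(body$out, model$params$head$W, model$params$head$b)
  sg <- sigmoid_fwd(hd$out)
  list(out = sg$out, cache = list(body = body$cache, head = hd, sig = sg))
}

nn_backward <- function(model, cache, dout) {
  ds <- sigmoid_bwd(dout, cache$sig$y)
  dh <- conv_bwd(ds, cache$head$x, model$params$head$W)
  grads <- list(enc = vector("list", model$spec$depth),
                dec = vector("list", max(model$spec$depth - 1, 0)),
                head = list(W = dh$dW, b = dh$db))
  res <- nn_bwd_level(dh$dx, cache$body, model$params, model$spec, 1L, grads)
  res$grads
}

#' Predict a score map for one image
#'
#' @param object an `rs_nn_model`.
#' @param image H x W x 3 array in \[0,1\]; H and W need not be
#'   multiples of 2^(depth-1) (odd extents are edge-padded internally).
#' @param channel output channel to report (two-channel models predict
#'   the mask in channel 1).
#' @param ... unused.
#' @return An `rs_scoremap` of the input's spatial shape.
#' @export
predict.rs_nn_model <- function(object, image, channel = 1, ...) {
  x <- array(image, c(dim(image)[1], dim(image)[2], 1, 3))
  out <- nn_forward(object, x)$out
  new_scoremap(out[, , 1, channel], paste0("nn_", object$spec$family))
}

#' Padded prediction with the 324-to-260 geometry
#'
#' Reflect-pads a standardized 256 x 256 input up to `in_size`, runs the
#' model, crops the prediction to `out_size`, then centre-crops again to
#' `eval_size` so the padding never enters evaluation. Two-channel
#' models contribute their mask channel.
#'
#' @param model an `rs_nn_model` of family `unet_gn_res`.
#' @param pair a standardized [rs_pair] (`eval_size` x `eval_size`).
#' @param in_size padded input side (default 324).
#' @param out_size model output side kept before evaluation cropping
#'   (default 260).
#' @param eval_size final evaluated side (default 256).
#' @return An `rs_scoremap` of `eval_size` x `eval_size`.
#' @export
predict_padded <- function(model, pair, in_size = 324, out_size = 260,
                           eval_size = 256) {
  if (!identical(model$spec$family, "unet_gn_res")) {
    stop("predict_padded implements the unet_gn_res geometry")
  }
  h <- dim(pair$image)[1]
  if (h != eval_size || dim(pair$image)[2] != eval_size) {
    stop(sprintf("expected a standardized %dx%d pair", eval_size, eval_size))
  }
  if (in_size < out_size || out_size < eval_size ||
      (in_size - out_size) %% 2 != 0 || (out_size - eval_size) %% 2 != 0) {
    stop("invalid padded-prediction geometry")
  }
  p <- (in_size - eval_size) %/% 2
  img <- pad_reflect_rgb(pair$image, p)
  x <- array(img, c(in_size, in_size, 1, 3))
  full <- nn_forward(model, x)$out              # in_size x in_size
  m1 <- (in_size - out_size) %/% 2
  stage <- full[m1 + seq_len(out_size), m1 + seq_len(out_size), 1, 1]
  m2 <- (out_size - eval_size) %/% 2
  new_scoremap(stage[m2 + seq_len(eval_size), m2 + seq_len(eval_size)],
               "unet_gn_res_padded")
}
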