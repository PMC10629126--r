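# Fourfold training-set expansion: one original plus horizontal flip,
# vertical flip and RGB channel flip, with random photometric jitter
# (Gaussian blur, vertical motion blur, brightening, darkening) riding
# on top of the flipped copies.

#' Augmentation policy
#'
#' @param photometric_prob probability, per transform and per copy, that
#'   each photometric perturbation is applied to a flipped copy's image.
#' @param blur_sigma_range Gaussian blur sigma range in px.
#' @param motion_blur_len_range vertical motion-blur kernel length range
#'   in px (odd lengths are drawn from inside it).
#' @param brightness_delta_range additive brightness magnitude range on
#'   the \[0,1\] intensity scale.
#' @param seed default seed used when expanding whole bundles.
#' @return A list of class `rs_augment_policy`.
#' @export
augment_policy <- function(photometric_prob = 0.5,
                           blur_sigma_range = c(0.5, 1.5),
                           motion_blur_len_range = c(3, 9),
                           brightness_delta_range = c(0.05, 0.25),
                           seed = 1) {
  stopifnot(photometric_prob >= 0, photometric_prob <= 1,
            all(blur_sigma_range >= 0), all(motion_blur_len_range >= 0),
            all(brightness_delta_range >= 0))
  structure(list(photometric_prob = photometric_prob,
                 blur_sigma_range = blur_sigma_range,
                 motion_blur_len_range = motion_blur_len_range,
                 brightness_delta_range = brightness_delta_range,
                 seed = seed),
            class = "rs_augment_policy")
}

flip_h <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
flip_v <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

flip_image <- function(image, what) {
  switch(what,
    h = image[, rev(seq_len(dim(image)[2])), , drop = FALSE],
    v = image[rev(seq_len(dim(image)[1])), , , drop = FALSE],
    channel = image[, , 3:1, drop = FALSE]
  )
}

#' Random photometric perturbation of an image
#'
#' Independently applies, each with probability `photometric_prob`:
#' Gaussian blur, vertical motion blur (uniform vertical kernel,
#' reflective boundaries), brightening, and darkening, simulating
#' unfocused or moving captures and varying illumination. The output is
#' clipped to \[0,1\]. Masks are never touched by this function.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param policy an [augment_policy()].
#' @param seed optional integer seed for a local RNG stream.
#' @return Perturbed image, same shape, values in \[0,1\].
#' @export
photometric_jitter <- function(image, policy, seed = NULL) {
  with_seed(seed, {
    p <- policy$photometric_prob
    if (runif(1) < p) {
      sigma <- runif(1, policy$blur_sigma_range[1], policy$blur_sigma_range[2])
      image <- gaussian_blur_rgb(image, sigma)
    }
    if (runif(1) < p) {
      lens <- seq(policy$motion_blur_len_range[1],
                  policy$motion_blur_len_range[2])
      len <- lens[sample.int(length(lens), 1)]
      if (len %% 2 == 0) len <- len + 1
      if (len > 1) {
        k <- rep(1 / len, len)
        for (ch in 1:3) image[, , ch] <- conv_sep(image[, , ch], k, 1)
      }
    }
    # clip after each additive step: saturation, like a real sensor
    if (runif(1) < p) {
      image <- clamp01(image + runif(1, policy$brightness_delta_range[1],
                                     policy$brightness_delta_range[2]))
    }
    if (runif(1) < p) {
      image <- clamp01(image - runif(1, policy$brightness_delta_range[1],
                                     policy$brightness_delta_range[2]))
    }
    clamp01(image)
  })
}

#' Expand one pair fourfold
#'
#' Returns `[original, horizontal flip, vertical flip, RGB channel
#' flip]`. Geometric flips are applied identically to image and mask;
#' the channel flip reverses the RGB order and leaves the mask
#' untouched. Photometric jitter is then applied independently to each
#' of the three flipped copies' images (the original is kept as-is);
#' masks and soil-only flags are preserved exactly.
#'
#' @param pair a standardized [rs_pair].
#' @param policy an [augment_policy()].
#' @param seed optional integer seed.
#' @return A list of 4 [rs_pair] objects.
#' @export
expand_fourfold <- function(pair, policy = augment_policy(), seed = NULL) {
  copies <- list(
    list(image = pair$image, mask = pair$mask, tag = "orig"),
    list(image = flip_image(pair$image, "h"), mask = flip_h(pair$mask), tag = "hflip"),
    list(image = flip_image(pair$image, "v"), mask = flip_v(pair$mask), tag = "vflip"),
    list(image = flip_image(pair$image, "channel"), mask = pair$mask, tag = "cflip")
  )
  out <- vector("list", 4)
  for (i in 1:4) {
    img <- copies[[i]]$image
    if (i > 1) {
      img <- photometric_jitter(img, policy,
                                seed = if (is.null(seed)) NULL else derive_seed(seed, i))
    }
    out[[i]] <- rs_pair(img, copies[[i]]$mask, pair$pixel_scale, pair$domain,
                        true_length_mm = pair$true_length_mm,
                        id = paste0(pair$id, "_", copies[[i]]$tag),
                        seed = pair$seed)
  }
  out
}

#' Expand every pair of a bundle fourfold
#'
#' @param bundle an `rs_bundle` of n pairs.
#' @param policy an [augment_policy()].
#' @param seed master seed; per-pair streams are derived from it.
#' @return An `rs_bundle` of 4n pairs.
#' @export
augment_bundle <- function(bundle, policy = augment_policy(), seed = policy$seed) {
  pairs <- bundle_pairs(bundle)
  out <- vector("list", 4 * length(pairs))
  for (i in seq_along(pairs)) {
    out[(4 * (i - 1) + 1):(4 * i)] <-
      expand_fourfold(pairs[[i]], policy, seed = derive_seed(seed, i))
  }
  res <- as_bundle(out)
  if ("split" %in% names(bundle)) res$split <- rep(bundle$split, each = 4)
  as_rs_bundle(res)
}
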