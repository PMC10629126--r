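#' Construct an image/mask pair
#'
#' The atomic record of the pipeline: an RGB minirhizotron image in
#' \[0,1\] with its binary root mask, the pixel-to-mm scale, and
#' provenance. Synthetic pairs additionally carry the ground-truth
#' summed centerline length in mm.
#'
#' @param image H x W x 3 numeric array with values in \[0,1\].
#' @param mask H x W matrix of 0/1 (same spatial shape as `image`).
#' @param pixel_scale mm per pixel, > 0.
#' @param domain device/style tag.
#' @param true_length_mm ground-truth root length in mm (synthetic
#'   scenes), `NA` when unknown.
#' @param id identifier string.
#' @param seed integer seed the pair was generated from, if any.
#' @return An object of class `rs_pair`.
#' @export
rs_pair <- function(image, mask, pixel_scale = 1, domain = "default",
                    true_length_mm = NA_real_, id = "img", seed = NA_integer_) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (!is.matrix(mask) || !identical(dim(mask), dim(image)[1:2])) {
    stop("mask must be a matrix with the same spatial shape as the image")
  }
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0/1")
  storage.mode(mask) <- "double"
  if (!is.numeric(pixel_scale) || pixel_scale <= 0) stop("pixel_scale must be > 0")
  rng <- range(image)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) stop("image values must lie in [0,1]")
  structure(
    list(image = image, mask = mask, pixel_scale = pixel_scale,
         domain = domain, soil_only = sum(mask) == 0,
         true_length_mm = true_length_mm, id = id, seed = seed),
    class = "rs_pair"
  )
}

#' @export
print.rs_pair <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<rs_pair %s> %dx%d px, domain=%s, soil_only=%s, scale=%g mm/px",
              x$id, d[1], d[2], x$domain, x$soil_only, x$pixel_scale))
  if (!is.na(x$true_length_mm)) cat(sprintf(", true length %.2f mm", x$true_length_mm))
  cat("\n")
  invisible(x)
}

#' Assemble pairs into a dataset bundle
#'
#' A bundle is a tibble with one row per image pair: list-columns for
#' the image and mask arrays plus plain columns for the metadata, so it
#' pipes through dplyr verbs. Optional `split` labels partition the
#' bundle into train/val/test.
#'
#' @param pairs list of [rs_pair] objects.
#' @return A tibble of class `rs_bundle`.
#' @export
as_bundle <- function(pairs) {
  stopifnot(length(pairs) >= 1, all(vapply(pairs, inherits, TRUE, "rs_pair")))
  out <- tibble::tibble(
    id = vapply(pairs, `[[`, "", "id"),
    image = lapply(pairs, `[[`, "image"),
    mask = lapply(pairs, `[[`, "mask"),
    pixel_scale = vapply(pairs, `[[`, 0, "pixel_scale"),
    domain = vapply(pairs, `[[`, "", "domain"),
    soil_only = vapply(pairs, `[[`, TRUE, "soil_only"),
    true_length_mm = vapply(pairs, `[[`, 0, "true_length_mm"),
    seed = vapply(pairs, function(p) as.integer(p$seed), 0L)
  )
  class(out) <- c("rs_bundle", class(out))
  out
}

#' Extract one row of a bundle as an `rs_pair`
#'
#' @param bundle an `rs_bundle` tibble.
#' @param i row index.
#' @return An [rs_pair].
#' @export
bundle_pair <- function(bundle, i) {
  rs_pair(bundle$image[[i]], bundle$mask[[i]], bundle$pixel_scale[i],
          bundle$domain[i], bundle$true_length_mm[i], bundle$id[i],
          bundle$seed[i])
}

#' Iterate over bundle rows as pairs
#'
#' @param bundle an `rs_bundle` tibble.
#' @return A list of [rs_pair] objects.
#' @export
bundle_pairs <- function(bundle) {
  lapply(seq_len(nrow(bundle)), function(i) bundle_pair(bundle, i))
}

# Reclass after dplyr verbs strip the subclass.
as_rs_bundle <- function(df) {
  if (!inherits(df, "rs_bundle")) class(df) <- c("rs_bundle", class(df))
  df
}

#' Per-domain composition of a bundle
#'
#' @param bundle an `rs_bundle`.
#' @return A tibble with columns `domain` and `n`; counts sum to
#'   `nrow(bundle)`.
#' @export
bundle_composition <- function(bundle) {
  dplyr::count(tibble::as_tibble(bundle), .data$domain, name = "n")
}
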