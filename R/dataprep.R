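# Dataset assembly: tiling large captures into focus-sized sections,
# rescaling to the common 256x256 working size, recurrent 1:9 splitting,
# and proportioned mixing of several sources into one set.

# Choose the rows x cols factorisation of n whose tile aspect ratio is
# closest to square for an h x w image.
best_grid <- function(n, h, w) {
  divs <- which(n %% seq_len(n) == 0)
  best <- NULL; best_score <- Inf
  for (r in divs) {
    cc <- n %/% r
    score <- abs(log((h / r) / (w / cc)))
    if (score < best_score) { best_score <- score; best <- c(r, cc) }
  }
  best
}

subset_pair <- function(pair, rows, cols, id_suffix) {
  img <- pair$image[rows, cols, , drop = FALSE]
  msk <- pair$mask[rows, cols, drop = FALSE]
  rs_pair(img, msk, pair$pixel_scale, pair$domain,
          true_length_mm = NA_real_,
          id = paste0(pair$id, id_suffix), seed = pair$seed)
}

#' Crop an image pair into a non-overlapping grid of tiles
#'
#' Splits the image into exactly `n_tiles` equal tiles arranged on the
#' rows x cols grid whose tiles are closest to square; trailing remainder
#' pixels that do not fill a whole tile are cropped. The mask is tiled
#' identically and the soil-only flag is recomputed per tile. Tile
#' ground-truth lengths are unknown (`NA`) because centerline length
#' does not distribute over crops.
#'
#' @param pair an [rs_pair].
#' @param n_tiles number of tiles; must factorise into a grid that fits
#'   the image.
#' @return An `rs_bundle` of `n_tiles` pairs in row-major tile order.
#' @export
tile_grid <- function(pair, n_tiles) {
  h <- dim(pair$image)[1]; w <- dim(pair$image)[2]
  if (n_tiles > h * w) stop("invalid grid: n_tiles exceeds pixel count")
  g <- best_grid(n_tiles, h, w)
  th <- h %/% g[1]; tw <- w %/% g[2]
  if (th < 1 || tw < 1) stop("invalid grid: tiles would be empty")
  pairs <- vector("list", n_tiles)
  k <- 0L
  for (r in seq_len(g[1])) {
    for (cc in seq_len(g[2])) {
      k <- k + 1L
      rows <- ((r - 1L) * th + 1L):(r * th)
      cols <- ((cc - 1L) * tw + 1L):(cc * tw)
      pairs[[k]] <- subset_pair(pair, rows, cols, sprintf("_t%02d", k))
    }
  }
  as_rs_bundle(as_bundle(pairs))
}

# Tile origins along one axis: k tiles of size t over extent n.
# If the grid span k*t covers n, origins spread evenly from 0 to n-t so
# neighbours overlap by equal amounts; otherwise tiles sit edge to edge
# with the uncovered margin split symmetrically.
tile_origins <- function(n, t, k) {
  if (k == 1) return(floor((n - t) / 2))
  if (k * t >= n) {
    round((0:(k - 1)) * (n - t) / (k - 1))
  } else {
    off <- floor((n - k * t) / 2)
    off + (0:(k - 1)) * t
  }
}

#' Crop an image pair into overlapping fixed-size tiles
#'
#' Produces exactly `n_tiles` tiles of exactly `tile_size`, placed on
#' the rows x cols grid that minimises uncovered area; when the grid
#' span exceeds the image the origins are spaced evenly so adjacent
#' tiles overlap, and when it falls short the margins are split
#' symmetrically.
#'
#' @param pair an [rs_pair].
#' @param tile_size integer (rows, cols) of each tile.
#' @param n_tiles number of tiles.
#' @return An `rs_bundle` of `n_tiles` pairs, each exactly `tile_size`.
#' @export
tile_overlapping <- function(pair, tile_size, n_tiles) {
  h <- dim(pair$image)[1]; w <- dim(pair$image)[2]
  th <- tile_size[1]; tw <- tile_size[2]
  if (th > h && tw > w) stop("invalid tile: tile_size exceeds image in both dimensions")
  if (th > h || tw > w) stop("invalid tile: tile_size exceeds image extent")
  divs <- which(n_tiles %% seq_len(n_tiles) == 0)
  best <- NULL; best_cov <- -1
  for (r in divs) {
    cc <- n_tiles %/% r
    cov <- min(r * th, h) * min(cc * tw, w)
    if (cov > best_cov) { best_cov <- cov; best <- c(r, cc) }
  }
  ro <- tile_origins(h, th, best[1])
  co <- tile_origins(w, tw, best[2])
  pairs <- vector("list", n_tiles)
  k <- 0L
  for (r in seq_len(best[1])) {
    for (cc in seq_len(best[2])) {
      k <- k + 1L
      pairs[[k]] <- subset_pair(pair, ro[r] + seq_len(th), co[cc] + seq_len(tw),
                                sprintf("_o%02d", k))
    }
  }
  as_rs_bundle(as_bundle(pairs))
}

#' Rescale a pair to the square working size
#'
#' Bilinear resize of the image to `size` x `size` with values kept in
#' \[0,1\]; the mask is resized with nearest-neighbour sampling and
#' re-binarised at 0.5 so it stays strictly 0/1. The mm-per-px scale is
#' multiplied by the mean of the per-axis resize factors.
#'
#' @param pair an [rs_pair].
#' @param size target side length in px (default 256).
#' @return A standardized [rs_pair].
#' @export
standardize <- function(pair, size = 256) {
  if (size < 1) stop("size must be >= 1")
  h <- dim(pair$image)[1]; w <- dim(pair$image)[2]
  if (h == size && w == size) return(pair)
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    img[, , ch] <- EBImage::imageData(
      EBImage::resize(EBImage::Image(pair$image[, , ch]), size, size))
  }
  msk <- EBImage::imageData(
    EBImage::resize(EBImage::Image(pair$mask), size, size, filter = "none"))
  msk <- (msk >= 0.5) * 1
  rs_pair(clamp01(img), msk,
          pixel_scale = pair$pixel_scale * mean(c(h, w) / size),
          domain = pair$domain, true_length_mm = pair$true_length_mm,
          id = pair$id, seed = pair$seed)
}

#' Standardize every pair in a bundle
#'
#' @param bundle an `rs_bundle`.
#' @param size target side length, see [standardize()].
#' @return An `rs_bundle` of standardized pairs.
#' @export
standardize_bundle <- function(bundle, size = 256) {
  out <- as_bundle(lapply(bundle_pairs(bundle), standardize, size = size))
  if ("split" %in% names(bundle)) out$split <- bundle$split
  as_rs_bundle(out)
}

#' Specification for recurrent splitting
#'
#' The set is first split between test and training-validation at
#' `test_ratio` (1:9 by default), then the remainder is split between
#' validation and training at `val_ratio_of_remainder`. Shares are
#' rounded half away from zero.
#'
#' @param test_ratio test share of the whole set, in (0,1).
#' @param val_ratio_of_remainder validation share of the non-test
#'   remainder, in (0,1).
#' @param seed shuffle seed.
#' @return A list of class `rs_split_spec`.
#' @export
split_spec <- function(test_ratio = 0.1, val_ratio_of_remainder = 0.1, seed = 1) {
  stopifnot(test_ratio > 0, test_ratio < 1,
            val_ratio_of_remainder > 0, val_ratio_of_remainder < 1)
  structure(list(test_ratio = test_ratio,
                 val_ratio_of_remainder = val_ratio_of_remainder,
                 seed = seed, rounding = "half-away-from-zero"),
            class = "rs_split_spec")
}

#' Recurrently split a bundle into train/validation/test
#'
#' Shuffles with the spec seed, labels `round(test_ratio * N)` items as
#' test, then `round(val_ratio * (N - test))` of the remainder as
#' validation, the rest as training. Labels are added as a `split`
#' column; every item gets exactly one label.
#'
#' @param bundle an `rs_bundle` with at least 3 rows.
#' @param spec an [split_spec()].
#' @return The bundle with a `split` column in the original row order.
#' @export
recurrent_split <- function(bundle, spec = split_spec()) {
  n <- nrow(bundle)
  if (is.null(n) || n == 0) stop("cannot split an empty bundle")
  if (n < 3) stop("bundle must contain at least 3 items")
  n_test <- round_half_up(spec$test_ratio * n)
  n_val <- round_half_up(spec$val_ratio_of_remainder * (n - n_test))
  ord <- with_seed(spec$seed, sample(n))
  split <- character(n)
  split[ord[seq_len(n_test)]] <- "test"
  split[ord[n_test + seq_len(n_val)]] <- "val"
  split[split == ""] <- "train"
  bundle$split <- split
  as_rs_bundle(bundle)
}

#' Mix several source bundles into one set with given proportions
#'
#' Samples without replacement from each named source; per-source counts
#' are `round(total * fraction)` with any rounding remainder assigned to
#' the source with the largest fraction. Domain composition is preserved
#' in the per-pair metadata.
#'
#' @param bundles named list of `rs_bundle`s.
#' @param proportions named fractions summing to 1 (names matching
#'   `bundles`).
#' @param total number of images in the mixed set.
#' @param seed sampling seed.
#' @return An `rs_bundle` of `total` pairs.
#' @export
mix_datasets <- function(bundles, proportions, total, seed = 1) {
  stopifnot(is.list(bundles), length(bundles) >= 1,
            setequal(names(bundles), names(proportions)))
  proportions <- unlist(proportions[names(bundles)])
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  counts <- round_half_up(total * unlist(proportions))
  rem <- total - sum(counts)
  big <- which.max(unlist(proportions))
  counts[big] <- counts[big] + rem
  taken <- vector("list", length(bundles))
  for (i in seq_along(bundles)) {
    nm <- names(bundles)[i]
    src <- bundles[[i]]
    if (nrow(src) < counts[i]) {
      stop(sprintf("source '%s' has %d images but %d requested", nm,
                   nrow(src), counts[i]))
    }
    idx <- with_seed(derive_seed(seed, i), sample(nrow(src), counts[i]))
    taken[[i]] <- src[sort(idx), ]
  }
  out <- dplyr::bind_rows(taken)
  as_rs_bundle(out)
}
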