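#' Built-in device domains for the synthetic generator
#'
#' Minirhizotron datasets differ by capture device and site: soil colour
#' palette, base brightness, contrast of the speckle texture, blur, and
#' strength of the multiplicative illumination gradient. Each named
#' domain bundles those style parameters, emulating the heterogeneity of
#' imaging campaigns without copying any real data.
#'
#' @return Named list of domain style lists.
#' @export
synth_domains <- function() {
  list(
    # coarse sandy red soil, bright white roots, sharp focus
    sandy_red = list(palette = c(0.45, 0.30, 0.22), brightness = 0.0,
                     contrast = 0.06, blur = 0.0, illum = 0.25,
                     root_polarity = "bright"),
    # beige loess, mild blur, moderate gradient
    loess = list(palette = c(0.55, 0.48, 0.38), brightness = 0.05,
                 contrast = 0.05, blur = 0.6, illum = 0.35,
                 root_polarity = "bright"),
    # dark wet soil with heavy shadows and blur (autofocus prototype)
    dark_wet = list(palette = c(0.28, 0.24, 0.20), brightness = -0.05,
                    contrast = 0.09, blur = 1.0, illum = 0.55,
                    root_polarity = "bright"),
    # potting mix with dark roots on a lighter background
    potting_dark_roots = list(palette = c(0.50, 0.42, 0.34), brightness = 0.02,
                              contrast = 0.07, blur = 0.4, illum = 0.30,
                              root_polarity = "dark")
  )
}

#' Describe a synthetic minirhizotron scene
#'
#' A recipe fixes everything `render_scene()` needs: image geometry, the
#' device domain style, how many roots to draw and how wide, the
#' densities of bright artefacts (stones/water droplets) and scratches,
#' whether the scene is soil-only, and the pixel scale.
#'
#' @param image_size integer (rows, cols), each >= 64.
#' @param domain domain name (see [synth_domains()]) or a style list.
#' @param n_roots_lambda Poisson mean for the root count (>= 1 root is
#'   always drawn for non-soil scenes).
#' @param root_width_range radius range in px, `c(min, max)` with
#'   `0 < min <= max`.
#' @param root_polarity `"bright"`, `"dark"`, or `NULL` to take the
#'   domain default.
#' @param artefact_density expected stones/droplets per image.
#' @param scratch_density expected scratches/foil lines per image.
#' @param soil_only logical; soil-only scenes contain no roots and have
#'   an all-zero mask.
#' @param pixel_scale mm per pixel, > 0.
#' @param seed integer seed or `NA`.
#' @return A list of class `rs_recipe`.
#' @export
scene_recipe <- function(image_size = c(256, 256), domain = "sandy_red",
                         n_roots_lambda = 2, root_width_range = c(2, 5),
                         root_polarity = NULL, artefact_density = 3,
                         scratch_density = 0.5, soil_only = FALSE,
                         pixel_scale = 0.1, seed = NA_integer_) {
  if (length(image_size) != 2 || any(image_size < 64)) {
    stop("image_size must be at least 64x64")
  }
  if (pixel_scale <= 0) stop("pixel_scale must be > 0")
  if (artefact_density < 0 || scratch_density < 0) stop("densities must be >= 0")
  if (length(root_width_range) != 2 || root_width_range[1] <= 0 ||
      root_width_range[1] > root_width_range[2]) {
    stop("invalid recipe: root_width_range must be 0 < min <= max")
  }
  style <- if (is.character(domain)) {
    doms <- synth_domains()
    if (!domain %in% names(doms)) stop("unknown domain: ", domain)
    doms[[domain]]
  } else domain
  structure(
    list(image_size = as.integer(image_size),
         domain = if (is.character(domain)) domain else "custom",
         style = style, n_roots_lambda = n_roots_lambda,
         root_width_range = root_width_range,
         root_polarity = root_polarity %||% style$root_polarity,
         artefact_density = artefact_density,
         scratch_density = scratch_density, soil_only = soil_only,
         pixel_scale = pixel_scale, seed = seed),
    class = "rs_recipe"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a random root centerline
#'
#' Draws a smooth random-walk polyline across the scene: a start point
#' on or near one image edge, a heading random-walked with small angular
#' increments, fixed step length, clipped when it leaves the frame.
#' Per-point radii random-walk inside `root_width_range`; per-point
#' brightness offsets wobble around a per-root base. The total polyline
#' arc length in px is recorded and is exactly the sum of consecutive
#' point distances.
#'
#' @param recipe an [scene_recipe()]; must not be soil-only.
#' @param seed optional integer seed for a local RNG stream.
#' @return A list of class `rs_trace` with `centerline` (n x 2 matrix of
#'   (row, col) positions, in px), `widths`, `intensity`,
#'   `arc_length_px`.
#' @export
sample_root_trace <- function(recipe, seed = NULL) {
  if (recipe$soil_only) stop("cannot sample a root trace for a soil-only recipe")
  with_seed(seed, {
    h <- recipe$image_size[1]; w <- recipe$image_size[2]
    step <- 2.5
    # start on a margin band, heading roughly toward the interior
    side <- sample(4, 1)
    start <- switch(side,
      c(runif(1, 1, h * 0.2), runif(1, 1, w)),       # top
      c(runif(1, h * 0.8, h), runif(1, 1, w)),       # bottom
      c(runif(1, 1, h), runif(1, 1, w * 0.2)),       # left
      c(runif(1, 1, h), runif(1, w * 0.8, w)))       # right
    heading <- switch(side,
      runif(1, pi / 4, 3 * pi / 4),                  # downwards
      runif(1, -3 * pi / 4, -pi / 4),                # upwards
      runif(1, -pi / 4, pi / 4),                     # rightwards
      runif(1, 3 * pi / 4, 5 * pi / 4))              # leftwards
    n_max <- ceiling(2 * (h + w) / step)
    pts <- matrix(NA_real_, n_max, 2)
    pts[1, ] <- start
    k <- 1L
    for (i in 2:n_max) {
      heading <- heading + rnorm(1, 0, 0.12)
      nxt <- pts[k, ] + step * c(sin(heading), cos(heading))
      if (nxt[1] < 1 || nxt[1] > h || nxt[2] < 1 || nxt[2] > w) break
      k <- k + 1L
      pts[k, ] <- nxt
    }
    if (k < 2L) {             # degenerate start: force a minimal segment
      k <- 2L
      pts[2, ] <- pmin(pmax(start + c(step, 0), 1), c(h, w))
    }
    pts <- pts[seq_len(k), , drop = FALSE]
    wr <- recipe$root_width_range
    widths <- numeric(k)
    widths[1] <- runif(1, wr[1], wr[2])
    if (k > 1) for (i in 2:k) {
      widths[i] <- min(max(widths[i - 1] + rnorm(1, 0, 0.08), wr[1]), wr[2])
    }
    base_int <- runif(1, 0.25, 0.45)
    intensity <- pmax(base_int + rnorm(k, 0, 0.02), 0.05)
    seg <- diff(pts)
    structure(
      list(centerline = pts, widths = widths, intensity = intensity,
           arc_length_px = sum(sqrt(rowSums(seg^2)))),
      class = "rs_trace"
    )
  })
}

# Rasterise one trace into additive intensity and mask layers. Discs of
# the local radius are stamped along a densely resampled centerline, so
# the mask is the union of tubes around the polyline.
stamp_trace <- function(trace, h, w) {
  layer <- matrix(0, h, w)
  mask <- matrix(0L, h, w)
  pts <- trace$centerline
  n <- nrow(pts)
  for (i in seq_len(max(n - 1, 1))) {
    p0 <- pts[i, ]; p1 <- pts[min(i + 1, n), ]
    d <- sqrt(sum((p1 - p0)^2))
    ts <- if (d < 1e-9) 0 else seq(0, 1, by = min(1, 0.5 / d))
    for (t in ts) {
      cpt <- p0 + t * (p1 - p0)
      rad <- trace$widths[i] + t * (trace$widths[min(i + 1, n)] - trace$widths[i])
      inten <- trace$intensity[i]
      r0 <- max(1L, floor(cpt[1] - rad)); r1 <- min(h, ceiling(cpt[1] + rad))
      c0 <- max(1L, floor(cpt[2] - rad)); c1 <- min(w, ceiling(cpt[2] + rad))
      if (r0 > r1 || c0 > c1) next
      rr <- r0:r1; cc <- c0:c1
      dist2 <- outer((rr - cpt[1])^2, (cc - cpt[2])^2, `+`)
      inside <- dist2 <= rad^2
      # soft radial profile on the image, hard disc in the mask
      prof <- inten * pmax(1 - dist2 / (rad + 0.5)^2, 0)
      layer[rr, cc] <- pmax(layer[rr, cc], prof * inside)
      mask[rr, cc][inside] <- 1L
    }
  }
  list(layer = layer, mask = mask)
}

# Low-frequency multiplicative illumination field: bilinearly
# interpolated coarse gain grid plus a random linear gradient, strength
# scaled by the domain's illum parameter.
illumination_field <- function(h, w, strength) {
  g <- matrix(runif(16, 1 - strength, 1 + strength), 4, 4)
  ri <- seq(1, 4, length.out = h); ci <- seq(1, 4, length.out = w)
  r0 <- pmin(floor(ri), 3); c0 <- pmin(floor(ci), 3)
  fr <- ri - r0; fc <- ci - c0
  f <- matrix(0, h, w)
  for (a in 0:1) for (b in 0:1) {
    wgt <- outer(if (a == 0) 1 - fr else fr, if (b == 0) 1 - fc else fc)
    f <- f + wgt * g[cbind(rep(r0 + a, w), rep(c0 + b, each = h))]
  }
  theta <- runif(1, 0, 2 * pi)
  grad <- outer(seq(-0.5, 0.5, length.out = h) * sin(theta),
                rep(1, w)) +
          outer(rep(1, h), seq(-0.5, 0.5, length.out = w) * cos(theta))
  f * (1 + strength * grad)
}

#' Render a synthetic minirhizotron scene
#'
#' Builds a soil background from the domain palette (low-frequency
#' multiplicative illumination times high-frequency speckle noise),
#' rasterises each sampled root as a tube of its local width (the mask is
#' the union of these tubes), then draws bright elliptical artefacts
#' (stones/droplets) and thin high-contrast scratches on the image only
#' -- artefacts never enter the mask. Soil-only recipes contain no roots
#' and return an all-zero mask.
#'
#' @param recipe an [scene_recipe()].
#' @param seed optional integer seed; defaults to `recipe$seed` when set.
#' @param id identifier for the resulting pair.
#' @return An [rs_pair] whose `true_length_mm` is the summed centerline
#'   arc length times `pixel_scale`.
#' @export
render_scene <- function(recipe, seed = NULL, id = "synth") {
  seed <- seed %||% (if (!is.na(recipe$seed)) recipe$seed else NULL)
  with_seed(seed, {
    h <- recipe$image_size[1]; w <- recipe$image_size[2]
    st <- recipe$style
    # soil background
    illum <- illumination_field(h, w, st$illum)
    image <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      speck <- matrix(rnorm(h * w, 0, st$contrast), h, w)
      image[, , ch] <- (st$palette[ch] + st$brightness + speck) * illum
    }
    mask <- matrix(0L, h, w)
    total_arc <- 0
    if (!recipe$soil_only) {
      n_roots <- max(1L, rpois(1, recipe$n_roots_lambda))
      dark <- identical(recipe$root_polarity, "dark")
      for (r in seq_len(n_roots)) {
        tr <- sample_root_trace(recipe)
        stamped <- stamp_trace(tr, h, w)
        total_arc <- total_arc + tr$arc_length_px
        mask[stamped$mask == 1L] <- 1L
        for (ch in 1:3) {
          # roots are slightly warm-white (or dark brown when polarity
          # is dark); channel weighting keeps G >= B so the vesselness
          # G-B preprocessing has signal
          cw <- c(1.0, 0.95, 0.75)[ch]
          delta <- stamped$layer * cw
          image[, , ch] <- image[, , ch] + (if (dark) -delta else delta)
        }
      }
    }
    # artefacts: bright ellipses then scratches, image only
    n_art <- rpois(1, recipe$artefact_density)
    for (a in seq_len(n_art)) {
      cy <- runif(1, 1, h); cx <- runif(1, 1, w)
      ay <- runif(1, 1.5, 6); ax <- runif(1, 1.5, 6)
      bright <- runif(1, 0.3, 0.55)
      r0 <- max(1L, floor(cy - ay)); r1 <- min(h, ceiling(cy + ay))
      c0 <- max(1L, floor(cx - ax)); c1 <- min(w, ceiling(cx + ax))
      if (r0 > r1 || c0 > c1) next
      rr <- r0:r1; cc <- c0:c1
      e <- outer((rr - cy)^2 / ay^2, (cc - cx)^2 / ax^2, `+`) <= 1
      for (ch in 1:3) image[rr, cc, ch] <- image[rr, cc, ch] + bright * e
    }
    n_scr <- rpois(1, recipe$scratch_density)
    for (s in seq_len(n_scr)) {
      p0 <- c(runif(1, 1, h), runif(1, 1, w))
      ang <- runif(1, 0, 2 * pi); len <- runif(1, 0.2, 0.8) * min(h, w)
      bright <- runif(1, -0.35, 0.45)
      ts <- seq(0, 1, length.out = ceiling(len))
      ry <- round(p0[1] + ts * len * sin(ang)); rx <- round(p0[2] + ts * len * cos(ang))
      keep <- ry >= 1 & ry <= h & rx >= 1 & rx <= w
      idx <- cbind(ry[keep], rx[keep])
      for (ch in 1:3) {
        m <- image[, , ch]; m[idx] <- m[idx] + bright; image[, , ch] <- m
      }
    }
    if (st$blur > 0) image <- gaussian_blur_rgb(image, st$blur)
    image <- clamp01(image)
    rs_pair(image, mask, pixel_scale = recipe$pixel_scale,
            domain = recipe$domain,
            true_length_mm = if (recipe$soil_only) 0 else total_arc * recipe$pixel_scale,
            id = id, seed = if (is.null(seed)) NA_integer_ else seed)
  })
}

#' Generate a reproducible synthetic dataset
#'
#' Renders `n` scenes from a pool of recipe templates, forcing exactly
#' `round(n * soil_fraction)` of them to be soil-only. Every image gets
#' its own RNG stream derived by hashing (master seed, image index), so
#' regeneration with the same arguments is byte-identical and individual
#' images can be re-rendered in isolation.
#'
#' @param recipes a single [scene_recipe()] or list of recipe templates,
#'   cycled over the images (their `soil_only` flag is overridden by the
#'   soil-fraction schedule).
#' @param n number of pairs, >= 1.
#' @param soil_fraction proportion of soil-only pairs in \[0,1\].
#' @param seed master integer seed.
#' @return An [as_bundle()] tibble of `n` pairs with
#'   `sum(soil_only) == round(n * soil_fraction)`.
#' @export
generate_dataset <- function(recipes, n, soil_fraction = 0.3, seed = 1) {
  if (n < 1) stop("empty request: n must be >= 1")
  if (soil_fraction < 0 || soil_fraction > 1) stop("soil_fraction must be in [0,1]")
  if (inherits(recipes, "rs_recipe")) recipes <- list(recipes)
  n_soil <- round_half_up(n * soil_fraction)
  # spread soil-only scenes deterministically across the bundle
  soil_at <- with_seed(derive_seed(seed, 0), sample(n, n_soil))
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    tmpl <- recipes[[((i - 1L) %% length(recipes)) + 1L]]
    tmpl$soil_only <- i %in% soil_at
    tmpl$seed <- NA_integer_
    pairs[[i]] <- render_scene(tmpl, seed = derive_seed(seed, i),
                               id = sprintf("synth_%04d", i))
  }
  as_rs_bundle(as_bundle(pairs))
}

#' Write a bundle to disk as PNG pairs plus a CSV manifest
#'
#' Images are 8-bit RGB PNGs, masks single-channel PNGs with root pixels
#' at 255. The manifest records file names, domain, soil-only flag,
#' pixel scale, ground-truth length, seed, and the split label when
#' present.
#'
#' @param bundle an `rs_bundle`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_files <- file.path(dir, paste0(bundle$id, ".png"))
  mask_files <- file.path(dir, paste0(bundle$id, "_mask.png"))
  for (i in seq_len(nrow(bundle))) {
    png::writePNG(bundle$image[[i]], img_files[i])
    png::writePNG(bundle$mask[[i]], mask_files[i])
  }
  manifest <- tibble::tibble(
    file = basename(img_files), mask_file = basename(mask_files),
    domain = bundle$domain, soil_only = bundle$soil_only,
    pixel_scale = bundle$pixel_scale,
    true_length_mm = bundle$true_length_mm, seed = bundle$seed,
    split = if ("split" %in% names(bundle)) bundle$split else NA_character_
  )
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir directory containing `manifest.csv` and the PNG pairs.
#' @return An `rs_bundle` tibble.
#' @export
read_bundle <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  pairs <- lapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(file.path(dir, man$file[i]))
    msk <- png::readPNG(file.path(dir, man$mask_file[i]))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    rs_pair(img, round(msk), pixel_scale = man$pixel_scale[i],
            domain = man$domain[i], true_length_mm = man$true_length_mm[i],
            id = sub("\\.png$", "", man$file[i]), seed = man$seed[i])
  })
  out <- as_bundle(pairs)
  if (!all(is.na(man$split))) out$split <- man$split
  as_rs_bundle(out)
}
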