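# Skeleton-based root length and the length regression.

test_that("thinning produces a subset skeleton of the expected length", {
  expect_equal(sum(skeletonize(matrix(0, 10, 10))), 0)
  # 100x5 horizontal bar: skeleton pixel count close to the bar length
  bar <- matrix(0, 20, 110)
  bar[8:12, 6:105] <- 1
  sk <- skeletonize(bar)
  # reference thinning (Zhang-Suen) yields 97 on this fixture; a couple
  # of pixels erode at each bar end
  expect_gte(sum(sk), 94)
  expect_lte(sum(sk), 102)
  expect_true(all(sk <= bar))          # no pixel created outside the mask
  expect_error(skeletonize(matrix(0.5, 4, 4)), "binary")
})

test_that("skeletons are one pixel wide across the bar", {
  bar <- matrix(0, 20, 60)
  bar[6:12, 5:55] <- 1
  sk <- skeletonize(bar)
  # every column in the bar's interior has at most 2 skeleton pixels
  expect_true(all(colSums(sk[, 10:50]) <= 2))
  expect_gte(sum(colSums(sk[, 10:50]) >= 1), 41)
})

test_that("length estimates convert pixel counts with the mm scale", {
  bar <- matrix(0, 10, 104)
  bar[5, 3:102] <- 1                    # already 1 px wide, 100 px long
  expect_equal(length_mm(bar, 0.1), 10.0)
  expect_equal(length_mm(matrix(0, 8, 8), 0.5), 0.0)
  expect_error(length_mm(bar, 0), "pixel_scale")
})

test_that("axis-aligned synthetic roots are recovered within 5%", {
  pair <- tube_pair(h = 64, w = 128, row = 32, radius = 2,
                    col_range = c(10, 118), pixel_scale = 0.15)
  est <- length_mm(pair$mask, pair$pixel_scale)
  expect_lt(abs(est - pair$true_length_mm) / pair$true_length_mm, 0.05)
})

test_that("diagonal roots show the documented pixel-count bias", {
  # 45-degree tube: plain pixel count under-measures by ~sqrt(2)
  n <- 80
  mask <- matrix(0, n + 10, n + 10)
  for (i in seq_len(n)) mask[4 + i + (-2:2), 4 + i] <- 1
  true_len <- (n - 1) * sqrt(2)          # px arc length of the diagonal
  plain <- length_mm(mask, 1)
  expect_lt(plain / true_len, 0.85)      # clearly under-measures
  expect_gt(plain / true_len, 1 / sqrt(2) - 0.1)
  weighted <- length_mm(mask, 1, diagonal_weighted = TRUE)
  expect_lt(abs(weighted - true_len) / true_len, 0.1)
})

test_that("dilating a tube changes the length estimate by less than 5%", {
  pair <- tube_pair(h = 48, w = 96, row = 24, radius = 2, col_range = c(8, 88))
  grow <- function(m) {
    g <- m
    g[-1, ] <- pmax(g[-1, ], m[-nrow(m), ])
    g[-nrow(m), ] <- pmax(g[-nrow(m), ], m[-1, ])
    g[, -1] <- pmax(g[, -1], m[, -ncol(m)])
    g[, -ncol(m)] <- pmax(g[, -ncol(m)], m[, -1])
    g
  }
  l0 <- length_mm(pair$mask, 1)
  l1 <- length_mm(grow(pair$mask), 1)
  expect_lt(abs(l1 - l0) / l0, 0.05)
})

test_that("length regression recovers exact linear relations", {
  rec <- tibble::tibble(image_id = as.character(1:10),
                        labelled_mm = seq(5, 50, by = 5),
                        predicted_mm = seq(5, 50, by = 5),
                        pixel_scale = 0.1)
  fit <- suppressWarnings(length_regression(rec))
  expect_equal(fit$slope, 1); expect_equal(fit$intercept, 0)
  expect_equal(fit$r2, 1)
  rec$predicted_mm <- 0.8 * rec$labelled_mm
  fit8 <- suppressWarnings(length_regression(rec))
  expect_equal(fit8$slope, 0.8); expect_equal(fit8$r2, 1)
  expect_error(length_regression(rec[1:2, ]), "at least 3")
  rec$labelled_mm <- 7
  expect_error(length_regression(rec), "degenerate")
})

test_that("noisy slope-0.8 simulations keep the true slope in the 95% CI", {
  set.seed(13)
  lab <- runif(200, 10, 100)
  rec <- tibble::tibble(image_id = as.character(1:200), labelled_mm = lab,
                        predicted_mm = 0.8 * lab + rnorm(200, 0, 4),
                        pixel_scale = 0.1)
  fit <- length_regression(rec)
  expect_gte(0.8, fit$ci95_slope[1])
  expect_lte(0.8, fit$ci95_slope[2])
  expect_gt(fit$r2, 0.9)
})

test_that("tidy and glance expose the broom-style summaries", {
  set.seed(2)
  lab <- runif(20, 5, 60)
  rec <- tibble::tibble(image_id = as.character(1:20), labelled_mm = lab,
                        predicted_mm = 0.9 * lab + rnorm(20, 0, 2),
                        pixel_scale = 0.1)
  fit <- length_regression(rec)
  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "slope"))
  expect_true(all(c("estimate", "conf.low", "conf.high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 20)
  expect_equal(gl$slope, fit$slope)
})

test_that("length records pair predictions with ground-truth skeletons", {
  p1 <- tube_pair(row = 20); p2 <- tube_pair(row = 40)
  b <- as_bundle(list(p1, p2))
  rec <- length_records(list(p1$mask, matrix(0, 64, 64)), b)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$predicted_mm[1], rec$labelled_mm[1])
  expect_equal(rec$predicted_mm[2], 0)
})
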