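# Tiling, rescaling, recurrent splitting and proportioned mixing.

test_that("grid tiling returns the exact tile counts of the source sets", {
  # scanner rhizotron captures: 2550x2273 -> 64 tiles
  t64 <- tile_grid(standin_pair(2550, 2273), 64)
  expect_equal(nrow(t64), 64)
  expect_true(all(vapply(t64$image, function(i) all(dim(i)[1:2] == c(318, 284)),
                         TRUE)))
  # rhizobox captures: 3991x1842 -> 32 tiles
  t32 <- tile_grid(standin_pair(3991, 1842), 32)
  expect_equal(nrow(t32), 32)
})

test_that("grid tiling conserves mask mass and covers without overlap", {
  pair <- tube_pair(h = 60, w = 80, row = 30, radius = 3)
  tiles <- tile_grid(pair, 4)
  expect_equal(nrow(tiles), 4)
  # cropped source = whole image here (60, 80 divisible by the 2x2 grid)
  expect_equal(sum(vapply(tiles$mask, sum, 0)), sum(pair$mask))
  expect_identical(tiles$soil_only,
                   vapply(tiles$mask, function(m) sum(m) == 0, TRUE))
  one <- tile_grid(pair, 1)
  expect_equal(one$image[[1]], pair$image)
  expect_error(tile_grid(tube_pair(h = 8, w = 8), 1e6), "invalid grid")
})

test_that("overlapping tiling yields exact counts, sizes and even overlaps", {
  # autumn/winter field captures: 2592x2944, 6 tiles of 972x972
  pair <- standin_pair(2592, 2944)
  tiles <- tile_overlapping(pair, c(972, 972), 6)
  expect_equal(nrow(tiles), 6)
  expect_true(all(vapply(tiles$image,
                         function(i) all(dim(i)[1:2] == c(972, 972)), TRUE)))
  # identity case
  small <- tube_pair(h = 64, w = 64)
  one <- tile_overlapping(small, c(64, 64), 1)
  expect_equal(one$image[[1]], small$image)
  expect_error(tile_overlapping(small, c(100, 100), 2), "invalid tile")
})

test_that("overlapping tile origins are evenly spaced with equal overlaps", {
  ns <- asNamespace("rootsegbench")
  # span exceeds extent: overlaps equal within 1 px of rounding
  org <- ns$tile_origins(100, 40, 3)
  expect_equal(length(org), 3)
  gaps <- diff(org)
  expect_true(max(gaps) - min(gaps) <= 1)
  expect_equal(org[1], 0); expect_equal(org[3], 60)
  # brute-force footprint: union covers the full extent when span >= n
  covered <- rep(FALSE, 100)
  for (o in org) covered[(o + 1):(o + 40)] <- TRUE
  expect_true(all(covered))
  # span short of extent: symmetric margins, edge-to-edge tiles
  org2 <- ns$tile_origins(100, 30, 3)
  expect_equal(diff(org2), c(30, 30))
  expect_equal(org2[1], 5)
})

test_that("standardize resizes, re-binarises and rescales pixel size", {
  pair <- tube_pair(h = 128, w = 128, row = 64, radius = 4)
  std <- standardize(pair, 64)
  expect_equal(dim(std$image), c(64, 64, 3))
  expect_true(all(std$mask %in% c(0, 1)))
  expect_gt(sum(std$mask), 0)
  expect_equal(std$pixel_scale, pair$pixel_scale * 2)
  expect_true(all(std$image >= 0 & std$image <= 1))
  # identity case
  expect_identical(standardize(pair, 128), pair)
  # saturation preserved
  allroot <- rs_pair(array(1, c(32, 32, 3)), matrix(1, 32, 32))
  expect_true(all(standardize(allroot, 16)$mask == 1))
})

test_that("recurrent splitting reproduces the 1:9 / 1:9 arithmetic", {
  b100 <- tiny_bundle(100)
  s100 <- recurrent_split(b100, split_spec(seed = 1))
  expect_equal(as.integer(table(s100$split)[c("train", "val", "test")]),
               c(81L, 9L, 10L))
  # the mixed-set size: round(68.7) = 69 test, round(61.8) = 62 val
  b687 <- tiny_bundle(687)
  s687 <- recurrent_split(b687, split_spec(seed = 2))
  expect_equal(as.integer(table(s687$split)[c("train", "val", "test")]),
               c(556L, 62L, 69L))
  # deterministic; labels partition the bundle
  s1 <- recurrent_split(tiny_bundle(10), split_spec(seed = 3))
  s2 <- recurrent_split(tiny_bundle(10), split_spec(seed = 3))
  expect_identical(s1$split, s2$split)
  expect_true(all(s1$split %in% c("train", "val", "test")))
  expect_error(recurrent_split(tiny_bundle(2), split_spec()), "at least 3")
})

test_that("mixing matches requested proportions with remainder to largest", {
  srcs <- list(a = tiny_bundle(400, domain = "a"),
               b = tiny_bundle(250, domain = "b"),
               c = tiny_bundle(150, domain = "c"))
  m100 <- mix_datasets(srcs, list(a = 0.5, b = 0.3, c = 0.2), 100, seed = 1)
  expect_equal(as.integer(table(m100$domain)[c("a", "b", "c")]), c(50L, 30L, 20L))
  m687 <- mix_datasets(srcs, list(a = 0.5, b = 0.3, c = 0.2), 687, seed = 1)
  expect_equal(as.integer(table(m687$domain)[c("a", "b", "c")]),
               c(344L, 206L, 137L))
  expect_equal(nrow(m687), 687)
  single <- mix_datasets(srcs["a"], list(a = 1.0), 40, seed = 2)
  expect_true(all(single$domain == "a"))
  expect_error(mix_datasets(srcs, list(a = 0.9, b = 0.05, c = 0.05), 500),
               "source 'a'")
})

test_that("dataset assembly reaches the documented 337 = 222 + 115 total", {
  roots <- tiny_bundle(222, domain = "rooted")
  soil <- tiny_bundle(115, domain = "soil")
  full <- mix_datasets(list(rooted = roots, soil = soil),
                       list(rooted = 222 / 337, soil = 115 / 337),
                       total = 337, seed = 1)
  expect_equal(nrow(full), 337)
  expect_equal(sum(full$domain == "soil"), 115)
})
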