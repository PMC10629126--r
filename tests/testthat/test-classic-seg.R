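# Dummy, Frangi vesselness (with preprocessing), adaptive thresholding
# and the pixel SVM.

test_that("dummy segmenter predicts no roots anywhere", {
  img <- tube_pair()$image
  sm <- dummy_segment(img)
  expect_true(all(sm$scores == 0))
  expect_identical(dim(sm$scores), dim(img)[1:2])
  # smoothed DSC against a 310-px mask is the documented 1/311
  truth <- matrix(0, 64, 64); truth[seq_len(310)] <- 1
  expect_equal(dsc(sm$scores, truth), 1 / 311, tolerance = 1e-12)
})

test_that("vesselness preprocessing extracts the G-B root contrast", {
  # constant-colour image -> constant output
  const <- array(rep(c(0.2, 0.5, 0.7), each = 32 * 32), c(32, 32, 3))
  out <- frangi_preprocess(const)
  expect_equal(max(out) - min(out), 0)
  # pure-green tube on pure-blue soil: tube brighter after G-B
  img <- array(0, c(32, 32, 3))
  img[, , 3] <- 1                    # blue soil
  img[14:18, 5:28, 2] <- 1           # green tube
  img[14:18, 5:28, 3] <- 0
  out <- frangi_preprocess(img)
  expect_gt(mean(out[14:18, 5:28]), mean(out[25:30, 5:28]))
  # output range stays inside [0,1] for random inputs
  set.seed(2)
  for (i in 1:3) {
    r <- frangi_preprocess(array(runif(24 * 24 * 3), c(24, 24, 3)))
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("vesselness vanishes on constant images and peaks on ridges", {
  expect_true(all(frangi_vesselness(matrix(0.5, 32, 32))$scores == 0))
  # bright ridge of width 4: response maximal on the centerline
  ch <- matrix(0, 48, 48)
  ch[23:26, ] <- 1
  v <- frangi_vesselness(ch, frangi_params(scales = c(1, 2, 3)))
  transect <- v$scores[, 24]
  expect_true(which.max(transect) %in% 23:26)
  expect_gt(mean(transect[23:26]), mean(transect[c(1:15, 34:48)]))
  expect_true(all(v$scores >= 0 & v$scores <= 1))
})

test_that("vesselness matches the brute-force reference implementation", {
  set.seed(4)
  ch <- matrix(runif(32 * 32), 32)
  ch <- rootsegbench:::conv_sep(ch, rootsegbench:::gaussian_kernel(1))
  ours <- frangi_vesselness(ch, frangi_params(scales = c(1, 2), beta = 0.5))
  ref <- naive_vesselness(ch, scales = c(1, 2), beta = 0.5)
  expect_lt(max(abs(ours$scores - ref)), 1e-6)
  # fixed-c variant too
  ours2 <- frangi_vesselness(ch, frangi_params(scales = 1.5, c = 0.05))
  ref2 <- naive_vesselness(ch, scales = 1.5, cfix = 0.05)
  expect_lt(max(abs(ours2$scores - ref2)), 1e-6)
})

test_that("vesselness is invariant to adding a constant", {
  set.seed(6)
  ch <- matrix(runif(24 * 24), 24)
  a <- frangi_vesselness(ch)$scores
  b <- frangi_vesselness(ch + 0.3)$scores
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("adaptive thresholding matches a sliding-window recomputation", {
  set.seed(8)
  img <- matrix(runif(121), 11)
  for (w in c("gaussian", "uniform")) {
    ours <- adaptive_threshold(img, adaptive_params(5, 0.02, w))$scores
    ref <- naive_adaptive(img, 5, 0.02, w)
    expect_identical(ours, ref)
  }
  expect_error(adaptive_params(10, 0.1), "odd")
})

test_that("constant images yield empty masks for positive offsets", {
  const <- array(0.5, c(32, 32, 3))
  expect_equal(sum(adaptive_threshold(const, adaptive_params(11, 0.01))$scores), 0)
})

test_that("local thresholding beats any global threshold under a gradient", {
  pair <- tube_pair(h = 64, w = 64, row = 32, radius = 2, bright = 0.18,
                    bg = 0.15, gradient = 0.7)
  grey <- rgb_to_grey(pair$image)
  # brute-force the best global threshold
  global_best <- max(vapply(seq(0.01, 0.99, by = 0.01), function(t) {
    dsc((grey > t) * 1, pair$mask, smooth = 0)
  }, 0))
  tuned <- tune_adaptive(adaptive_grid(),
                         as_bundle(list(pair)))
  local_dsc <- dsc(adaptive_threshold(pair$image, tuned)$scores, pair$mask,
                   smooth = 0)
  expect_lt(global_best, 0.5)
  expect_gt(local_dsc, 0.8)
})

test_that("tuning returns the grid argmax with deterministic tie-breaks", {
  pair <- tube_pair()
  val <- as_bundle(list(pair))
  grid1 <- data.frame(block_size = 15, offset = 0.05)
  t1 <- tune_adaptive(grid1, val)
  expect_equal(t1$block_size, 15)
  # exhaustive evaluation is the oracle: the tuned point achieves the
  # maximum mean DSC over the grid
  grid <- expand.grid(block_size = c(11, 19, 27), offset = c(0, 0.02, 0.05))
  best <- tune_adaptive(grid, val)
  all_dsc <- vapply(seq_len(nrow(grid)), function(i) {
    p <- adaptive_params(grid$block_size[i], grid$offset[i])
    dsc(adaptive_threshold(pair$image, p)$scores, pair$mask)
  }, 0)
  got <- dsc(adaptive_threshold(pair$image, best)$scores, pair$mask)
  expect_equal(got, max(all_dsc))
  expect_identical(tune_adaptive(grid, val), tune_adaptive(grid, val))
  expect_error(tune_adaptive(grid[0, ], val), "empty")
})

test_that("pixel SVM separates linearly separable colours perfectly", {
  img <- array(0, c(16, 16, 3))
  mask <- matrix(0, 16, 16); mask[5:10, 5:10] <- 1
  for (ch in 1:3) img[, , ch] <- mask          # white roots, black soil
  train <- as_bundle(list(rs_pair(img, mask, id = "sep")))
  fit <- svm_fit(train, svm_config(kernel = "linear", C = 10, seed = 1))
  pred <- predict_svm(fit, img)
  expect_identical(dim(pred$scores), c(16L, 16L))
  expect_true(all(pred$scores %in% c(0, 1)))
  expect_equal(pred$scores, mask)
  # single-class data is rejected
  bad <- as_bundle(list(rs_pair(img, matrix(0, 16, 16))))
  expect_error(svm_fit(bad, svm_config(seed = 1)), "degenerate labels")
})

test_that("pixel features flatten spatial dimensions by colour channels", {
  ns <- asNamespace("rootsegbench")
  img <- array(seq(0, 1, length.out = 48), c(4, 4, 3))
  f <- ns$pixel_features(img)
  expect_identical(dim(f), c(16L, 3L))
  expect_equal(f[, 1], as.numeric(img[, , 1]))
})

test_that("random search returns the best validated trial", {
  p1 <- tube_pair(row = 20); p2 <- tube_pair(row = 44)
  train <- as_bundle(list(p1)); val <- as_bundle(list(p2))
  cfg <- svm_config(n_trials = 5, pixel_subsample = 300, seed = 3)
  res <- svm_random_search(train, val, cfg)
  expect_equal(nrow(res$trials), 5)
  expect_true(all(is.na(res$trials$val_dsc) |
                    res$trials$val_dsc <= res$val_dsc + 1e-12))
  # n_trials = 1 returns that single config
  one <- svm_random_search(train, val, svm_config(n_trials = 1, seed = 4,
                                                  pixel_subsample = 200))
  expect_equal(nrow(one$trials), 1)
})
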