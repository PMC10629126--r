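# Overlap metrics, SSIM, image-level FPR, ROC.

test_that("DSC matches its closed forms", {
  m <- matrix(0, 20, 20); m[5:8, 5:12] <- 1
  expect_equal(dsc(m, m, smooth = 0), 1.0)
  a <- matrix(0, 2, 2); a[1, 1] <- 1; a[1, 2] <- 1   # |A| = 2
  b <- matrix(0, 2, 2); b[1, 1] <- 1; b[2, 1] <- 1   # |B| = 2, overlap 1
  expect_equal(dsc(a, b, smooth = 0), 0.5)
  # all-zero prediction vs a 310-px mask: smoothed score 1/311
  truth <- matrix(0, 64, 64); truth[seq_len(310)] <- 1
  expect_equal(dsc(matrix(0, 64, 64), truth, smooth = 1), 1 / 311)
  # empty vs empty under smoothing is perfect agreement
  expect_equal(dsc(matrix(0, 4, 4), matrix(0, 4, 4), smooth = 1), 1.0)
  expect_error(dsc(matrix(0, 4, 4), matrix(0, 4, 4), smooth = 0), "undefined")
  expect_error(dsc(matrix(0, 4, 4), matrix(0, 5, 5)), "shape")
})

test_that("IoU relates to DSC algebraically and equals it at zero overlap", {
  a <- matrix(0, 2, 2); a[1, ] <- 1
  b <- matrix(0, 2, 2); b[, 1] <- 1
  d0 <- dsc(a, b, smooth = 0)
  expect_equal(iou(a, b, smooth = 0), d0 / (2 - d0))
  # zero-intersection: smoothed IoU == smoothed DSC
  p <- matrix(0, 10, 10); p[1, 1] <- 1
  t <- matrix(0, 10, 10); t[5:9, 5:9] <- 1
  expect_equal(iou(p * 0, t, smooth = 1), dsc(p * 0, t, smooth = 1))
  expect_equal(iou(t, t), 1.0)
})

test_that("DSC and IoU are symmetric and flip-invariant", {
  set.seed(1)
  for (i in 1:5) {
    a <- matrix(rbinom(100, 1, 0.3), 10)
    b <- matrix(rbinom(100, 1, 0.3), 10)
    expect_equal(dsc(a, b), dsc(b, a))
    expect_equal(iou(a, b), iou(b, a))
    expect_equal(dsc(a[10:1, ], b[10:1, ]), dsc(a, b))
  }
})

test_that("SSIM agrees with a windowed brute-force recomputation", {
  expect_equal(ssim_index(matrix(0.4, 16, 16), matrix(0.4, 16, 16)), 1.0)
  set.seed(7)
  for (i in 1:3) {
    x <- matrix(runif(32 * 32), 32)
    y <- matrix(runif(32 * 32), 32)
    expect_equal(ssim_index(x, y), naive_ssim(x, y), tolerance = 1e-6)
  }
})

test_that("SSIM of independent noise is near zero, identical images 1", {
  set.seed(11)
  vals <- replicate(6, {
    x <- matrix(runif(64 * 64), 64)
    y <- matrix(runif(64 * 64), 64)
    ssim_index(x, y)
  })
  expect_true(all(abs(vals) < 0.1))
  x <- matrix(runif(64 * 64), 64)
  expect_equal(ssim_index(x, x), 1.0)
})

test_that("image-level FPR counts flagged soil-only images", {
  soil <- replicate(22, matrix(0, 8, 8), simplify = FALSE)
  flag_k <- function(k) {
    preds <- replicate(22, matrix(0, 8, 8), simplify = FALSE)
    for (i in seq_len(k)) preds[[i]][1, 1] <- 1
    if (k == 0) preds[[1]][1, 1] <- 0
    preds
  }
  # a never-predicting method is excluded, not scored zero
  r0 <- image_level_fpr(flag_k(0), soil)
  expect_true(r0$excluded)
  expect_true(is.na(r0$fpr))
  for (k in c(1, 5, 22)) {
    r <- image_level_fpr(flag_k(k), soil)
    expect_false(r$excluded)
    expect_equal(r$fpr, k / 22)
  }
  expect_error(image_level_fpr(list(matrix(1, 2, 2)), list(matrix(1, 2, 2))),
               "undefined rate")
})

test_that("ROC endpoints, monotonicity and analytic AUCs hold", {
  set.seed(3)
  truth <- matrix(rbinom(4096, 1, 0.2), 64)
  # perfect scores: AUC 1 and the curve passes (0, 1)
  perfect <- roc_curve(truth * 1, truth)
  expect_equal(perfect$auc, 1.0)
  expect_true(any(perfect$curve$fpr == 0 & perfect$curve$tpr == 1))
  # constant (dummy) scores: diagonal, AUC 0.5
  dummy <- roc_curve(matrix(0, 64, 64), truth)
  expect_equal(dummy$auc, 0.5)
  # curve is monotone from (0,0) to (1,1)
  sc <- matrix(runif(4096), 64)
  r <- roc_curve(sc, truth)
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_equal(r$curve$tpr[1], 0); expect_equal(r$curve$fpr[1], 0)
  expect_equal(tail(r$curve$tpr, 1), 1); expect_equal(tail(r$curve$fpr, 1), 1)
  expect_error(roc_curve(sc, matrix(0, 64, 64)), "single class")
})

test_that("ROC agrees with an independent implementation on shared thresholds", {
  skip_if_not_installed("pROC")
  set.seed(5)
  truth <- matrix(rbinom(2500, 1, 0.3), 50)
  scores <- matrix(runif(2500), 50)
  scores[truth == 1] <- scores[truth == 1]^0.5   # informative scores
  ours <- roc_curve(scores, truth, n_thresholds = 2048)
  ref <- pROC::roc(as.numeric(truth), as.numeric(scores), quiet = TRUE,
                   direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 5e-3)
})

test_that("binarisation is monotone in the threshold", {
  set.seed(9)
  ns <- asNamespace("rootsegbench")
  s <- matrix(runif(400), 20)
  m_lo <- ns$binarize(s, 0.3)
  m_hi <- ns$binarize(s, 0.7)
  expect_true(all(m_hi <= m_lo))   # higher threshold -> subset mask
})

test_that("evaluate_method reproduces hand-computed averages", {
  p1 <- tube_pair(row = 20); p2 <- tube_pair(row = 40)
  soil <- rs_pair(array(0.3, c(64, 64, 3)), matrix(0, 64, 64), id = "soil")
  bundle <- as_bundle(list(p1, p2, soil))
  scores <- list(p1$mask * 1, matrix(0, 64, 64), matrix(0, 64, 64))
  row <- evaluate_method(scores, bundle, method = "byhand")
  hand_dsc <- mean(c(dsc(p1$mask, p1$mask),
                     dsc(matrix(0, 64, 64), p2$mask),
                     dsc(matrix(0, 64, 64), matrix(0, 64, 64))))
  expect_equal(row$mean_dsc, hand_dsc)
  expect_equal(row$n_images, 3L)
  expect_equal(row$n_soil_only, 1L)
  expect_false(row$fpr_excluded)      # this method does predict roots
  expect_equal(row$fpr, 0)            # but not on the soil-only image
  # perfect predictor
  perfect <- evaluate_method(list(p1$mask * 1, p2$mask * 1,
                                  matrix(0, 64, 64)), bundle, "perfect")
  expect_equal(perfect$mean_dsc, 1.0)
  expect_equal(perfect$mean_iou, 1.0)
  expect_equal(perfect$mean_ssim, 1.0)
  expect_equal(perfect$fpr, 0.0)
})

test_that("dummy mean smoothed DSC approaches the soil-only fraction", {
  b <- generate_dataset(scene_recipe(image_size = c(64, 64)),
                        n = 30, soil_fraction = 0.3, seed = 21)
  scores <- lapply(b$image, function(i) dummy_segment(i)$scores)
  row <- evaluate_method(scores, b, method = "dummy")
  f <- mean(b$soil_only)
  expect_gte(row$mean_dsc, f)
  expect_lt(row$mean_dsc, f + 0.05)
  expect_equal(row$mean_dsc, row$mean_iou)
  expect_true(row$fpr_excluded)
})
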