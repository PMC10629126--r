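# Encoder-decoder models: construction, losses, gradients, training
# loop contracts, padded prediction geometry.

test_that("models emit sigmoid score maps of the input shape", {
  img <- tube_pair()$image
  for (fam in c("backboned_unet", "unet_gn_res", "segnet_style")) {
    oc <- if (fam == "unet_gn_res") 2 else 1
    m <- build_model(model_spec(fam, base_width = 4, depth = 2,
                                out_channels = oc, seed = 1))
    sm <- predict(m, img)
    expect_identical(dim(sm$scores), c(64L, 64L))
    expect_true(all(sm$scores > 0 & sm$scores < 1))
  }
  expect_error(model_spec("backboned_unet", encoder = "resnet"),
               "configuration error")
})

test_that("two-channel head trains toward the mask and its negative", {
  b <- generate_dataset(scene_recipe(image_size = c(64, 64)), n = 12,
                        soil_fraction = 0.25, seed = 3)
  b <- recurrent_split(standardize_bundle(b, 32), split_spec(seed = 1))
  m <- build_model(model_spec("unet_gn_res", base_width = 4, depth = 2,
                              out_channels = 2, seed = 1))
  fit <- train_model(m, b, train_config(loss = "dice_plus_ce",
                                        optimizer = "sgd_nesterov", lr = 0.005,
                                        epochs = 6, batch_size = 4, seed = 2))
  ns <- asNamespace("rootsegbench")
  pair <- bundle_pair(b, which(!b$soil_only & b$split == "train")[1])
  x <- array(pair$image, c(32, 32, 1, 3))
  out <- ns$nn_forward(fit$model, x)$out
  # channel 1 correlates with the mask, channel 2 with its complement
  expect_gt(cor(as.numeric(out[, , 1, 1]), as.numeric(pair$mask)), 0)
  expect_gt(cor(as.numeric(out[, , 1, 2]), as.numeric(1 - pair$mask)), 0)
})

test_that("parameter count strictly increases with base width", {
  n8 <- n_parameters(build_model(model_spec("backboned_unet", base_width = 8)))
  n16 <- n_parameters(build_model(model_spec("backboned_unet", base_width = 16)))
  expect_gt(n16, n8)
})

test_that("losses hit their analytic anchors", {
  t <- matrix(0, 8, 8); t[3:5, 2:7] <- 1
  expect_equal(loss_value("one_minus_dice", t, t), 0)
  expect_equal(loss_value("one_minus_ssim", t, t), 0)
  # inverted binary prediction: zero overlap, loss -> 1 (up to smoothing:
  # |pred| = 46, |target| = 18, so dice = 1/65)
  expect_equal(loss_value("one_minus_dice", 1 - t, t), 1 - 1 / 65)
  expect_error(loss_value("one_minus_dice", t, matrix(0, 4, 4)), "mismatch")
})

test_that("dice_plus_ce matches hand arithmetic on a 2x2 toy", {
  eps <- 0.05
  t <- matrix(c(1, 0, 0, 1), 2)
  p <- matrix(c(1 - eps, eps, eps, 1 - eps), 2)
  # soft dice: num = 2 * (2 * 0.95) + 1, den = 2 + 2 + 1
  dice <- (2 * (2 * (1 - eps)) + 1) / ((2 * (1 - eps) + 2 * eps) + 2 + 1)
  ce <- -mean(c(log(1 - eps), log(1 - eps), log(1 - eps), log(1 - eps)))
  expect_equal(loss_value("dice_plus_ce", p, t), (1 - dice) + ce,
               tolerance = 1e-12)
  # pred == target in {eps, 1-eps}: approaches the CE floor
  pe <- matrix(c(1 - 1e-6, 1e-6, 1e-6, 1 - 1e-6), 2)
  expect_lt(loss_value("dice_plus_ce", pe, t), 1e-4)
})

test_that("analytic gradients match finite differences for every loss", {
  ns <- asNamespace("rootsegbench")
  m <- build_model(model_spec("unet_gn_res", base_width = 4, depth = 2,
                              out_channels = 2, seed = 3))
  set.seed(1)
  x <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  t <- array((runif(8 * 8 * 2 * 2) > 0.5) * 1, c(8, 8, 2, 2))
  p <- ns$flatten_params(m$params)
  for (loss in c("one_minus_dice", "dice_plus_ce", "one_minus_ssim")) {
    fw <- ns$nn_forward(m, x)
    g <- ns$flatten_like(m$params,
                         ns$nn_backward(m, fw$cache,
                                        ns$nn_loss(loss, fw$out, t)$grad))
    set.seed(9)
    for (i in sample(length(p), 8)) {
      fd <- vapply(c(1e-5, -1e-5), function(eps) {
        mm <- m
        pp <- p; pp[i] <- pp[i] + eps
        mm$params <- ns$unflatten_into(m$params, pp)
        ns$nn_loss(loss, ns$nn_forward(mm, x)$out, t)$value
      }, 0)
      expect_equal(g[i], (fd[1] - fd[2]) / 2e-5, tolerance = 1e-4)
    }
  }
})

test_that("training logs every epoch and returns the argmax checkpoint", {
  b <- generate_dataset(scene_recipe(image_size = c(64, 64)), n = 16,
                        soil_fraction = 0.25, seed = 5)
  b <- recurrent_split(standardize_bundle(b, 32), split_spec(seed = 1))
  m <- build_model(model_spec("backboned_unet", base_width = 4, depth = 2,
                              seed = 1))
  cfg <- train_config(loss = "one_minus_dice", lr = 0.005, epochs = 5,
                      batch_size = 4, seed = 7)
  fit <- train_model(m, b, cfg)
  expect_equal(nrow(fit$history), 5)
  expect_equal(fit$best_score, max(fit$history$selection))
  expect_equal(fit$history$selection[fit$best_epoch], fit$best_score)
  expect_true(all(is.finite(fit$history$train_loss)))
})

test_that("training is reproducible under a fixed seed", {
  b <- generate_dataset(scene_recipe(image_size = c(64, 64)), n = 12,
                        soil_fraction = 0.25, seed = 6)
  b <- recurrent_split(standardize_bundle(b, 32), split_spec(seed = 2))
  cfg <- train_config(loss = "one_minus_dice", lr = 0.005, epochs = 3,
                      batch_size = 4, seed = 11)
  f1 <- train_model(build_model(model_spec("backboned_unet", base_width = 4,
                                           depth = 2, seed = 4)), b, cfg)
  f2 <- train_model(build_model(model_spec("backboned_unet", base_width = 4,
                                           depth = 2, seed = 4)), b, cfg)
  expect_identical(f1$history, f2$history)
})

test_that("cosine annealing follows its closed form and never increases", {
  b <- generate_dataset(scene_recipe(image_size = c(64, 64)), n = 12,
                        soil_fraction = 0.25, seed = 8)
  b <- recurrent_split(standardize_bundle(b, 32), split_spec(seed = 1))
  cfg <- train_config(loss = "one_minus_dice", lr = 0.01,
                      scheduler = "cosine_annealing", epochs = 6,
                      batch_size = 4, seed = 1)
  fit <- train_model(build_model(model_spec("backboned_unet", base_width = 4,
                                            depth = 2, seed = 1)), b, cfg)
  expected <- vapply(1:6, function(e) cosine_lr(0.01, e, 6), 0)
  expect_equal(fit$history$lr, expected)
  expect_true(all(diff(fit$history$lr) <= 0))
})

test_that("padded prediction respects the 324/260/256 geometry", {
  m <- build_model(model_spec("unet_gn_res", base_width = 4, depth = 3,
                              out_channels = 2, seed = 2))
  pair <- standardize(render_scene(scene_recipe(image_size = c(256, 256)),
                                   seed = 1), 256)
  sm <- predict_padded(m, pair)
  expect_identical(dim(sm$scores), c(256L, 256L))
  # the crop is centred: re-running on a shifted reflection would move
  # content; instead check the direct correspondence with the full map
  ns <- asNamespace("rootsegbench")
  img <- ns$pad_reflect_rgb(pair$image, 34)
  full <- ns$nn_forward(m, array(img, c(324, 324, 1, 3)))$out[, , 1, 1]
  expect_equal(sm$scores, full[34 + 1:256, 34 + 1:256])
  expect_error(predict_padded(build_model(model_spec("backboned_unet")),
                              pair), "unet_gn_res")
  small <- standardize(pair, 64)
  expect_error(predict_padded(m, small), "standardized")
})
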