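# Pixel-wise maximum-margin segmentation: each image is flattened to a
# (height*width) x 3 matrix of RGB features, a support-vector machine is
# fitted on a balanced pixel subsample, and predictions are reshaped
# back onto the image grid.

#' SVM configuration
#'
#' @param kernel `"linear"` or `"radial"`.
#' @param C regularisation weight (> 0).
#' @param max_iter solver effort cap; mapped onto the quadratic-
#'   programming convergence tolerance (`10 / max_iter`), since the
#'   underlying solver is tolerance- rather than iteration-bounded.
#' @param gamma RBF kernel width (radial kernel only).
#' @param n_trials random-search size for [svm_random_search()].
#' @param pixel_subsample maximum training pixels drawn per image.
#' @param seed integer seed.
#' @return A list of class `rs_svm_config`.
#' @export
svm_config <- function(kernel = "radial", C = 1, max_iter = 1e4, gamma = 1,
                       n_trials = 100, pixel_subsample = 2000, seed = 1) {
  if (C <= 0) stop("C must be > 0")
  if (n_trials < 1) stop("n_trials must be >= 1")
  structure(list(kernel = kernel, C = C, max_iter = max_iter, gamma = gamma,
                 n_trials = n_trials, pixel_subsample = pixel_subsample,
                 seed = seed),
            class = "rs_svm_config")
}

# Flatten an image to the (H*W) x 3 pixel-feature matrix.
pixel_features <- function(image) {
  matrix(image, nrow = prod(dim(image)[1:2]), ncol = 3)
}

# Balanced pixel subsample from one pair: up to n/2 root and n/2
# background pixels (topped up from the other class when one is short).
sample_pixels <- function(pair, n) {
  feats <- pixel_features(pair$image)
  lab <- as.integer(pair$mask)
  pos <- which(lab == 1); neg <- which(lab == 0)
  n_pos <- min(length(pos), n %/% 2)
  n_neg <- min(length(neg), n - n_pos)
  idx <- c(if (n_pos > 0) pos[sample.int(length(pos), n_pos)],
           if (n_neg > 0) neg[sample.int(length(neg), n_neg)])
  list(x = feats[idx, , drop = FALSE], y = lab[idx])
}

#' Fit a pixel-wise SVM segmenter
#'
#' @param train training `rs_bundle`; masks must contain both classes
#'   after subsampling.
#' @param cfg an [svm_config()].
#' @return An object of class `rs_svm` wrapping the fitted classifier.
#' @export
svm_fit <- function(train, cfg = svm_config()) {
  with_seed(cfg$seed, {
    parts <- lapply(bundle_pairs(train), sample_pixels, n = cfg$pixel_subsample)
    x <- do.call(rbind, lapply(parts, `[[`, "x"))
    y <- unlist(lapply(parts, `[[`, "y"))
    if (length(unique(y)) < 2) {
      stop("degenerate labels: training pixels contain a single class")
    }
    fit <- e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                      kernel = cfg$kernel, cost = cfg$C,
                      gamma = if (cfg$kernel == "radial") cfg$gamma else 1 / ncol(x),
                      tolerance = min(0.1, 10 / cfg$max_iter),
                      scale = FALSE)
    structure(list(fit = fit, config = cfg), class = "rs_svm")
  })
}

#' Predict a score map with a fitted pixel SVM
#'
#' @param object an `rs_svm`.
#' @param image H x W x 3 array.
#' @param ... unused.
#' @return A binary-valued `rs_scoremap` of the image's shape.
#' @export
predict_svm <- function(object, image, ...) {
  feats <- pixel_features(image)
  pred <- as.integer(as.character(predict(object$fit, feats)))
  new_scoremap(matrix(pred, dim(image)[1], dim(image)[2]), "svm")
}

#' @export
predict.rs_svm <- function(object, newdata, ...) predict_svm(object, newdata, ...)

#' Random hyperparameter search for the pixel SVM
#'
#' Samples `cfg$n_trials` configurations -- kernel from {linear,
#' radial}, `C` log-uniform in \[1e-2, 1e2\], `gamma` log-uniform in
#' \[0.1, 10\], solver effort from {1e3, 1e4, 1e5} -- fits each on the
#' training bundle and scores mean smoothed DSC on the validation
#' bundle. Failed fits are skipped; the best surviving configuration is
#' returned with its classifier and the full trial log.
#'
#' @param train,val training and validation `rs_bundle`s.
#' @param cfg an [svm_config()]; `n_trials` and `seed` drive the search.
#' @return A list with `classifier` (`rs_svm`), `config`, `val_dsc`,
#'   and `trials` (a tibble logging every trial).
#' @export
svm_random_search <- function(train, val, cfg = svm_config()) {
  draws <- with_seed(cfg$seed, {
    tibble::tibble(
      kernel = sample(c("linear", "radial"), cfg$n_trials, replace = TRUE),
      C = 10^runif(cfg$n_trials, -2, 2),
      gamma = 10^runif(cfg$n_trials, -1, 1),
      max_iter = sample(c(1e3, 1e4, 1e5), cfg$n_trials, replace = TRUE)
    )
  })
  val_pairs <- bundle_pairs(val)
  score_one <- function(model) {
    mean(vapply(val_pairs, function(p) {
      dsc(predict_svm(model, p$image)$scores, p$mask)
    }, 0))
  }
  results <- numeric(cfg$n_trials)
  models <- vector("list", cfg$n_trials)
  for (i in seq_len(cfg$n_trials)) {
    trial_cfg <- svm_config(draws$kernel[i], draws$C[i], draws$max_iter[i],
                            draws$gamma[i], cfg$n_trials,
                            cfg$pixel_subsample, derive_seed(cfg$seed, i))
    models[[i]] <- tryCatch(svm_fit(train, trial_cfg), error = function(e) NULL)
    results[i] <- if (is.null(models[[i]])) NA_real_ else score_one(models[[i]])
  }
  if (all(is.na(results))) stop("all SVM trials failed")
  best <- which.max(results)
  list(classifier = models[[best]], config = models[[best]]$config,
       val_dsc = results[best],
       trials = dplyr::mutate(draws, val_dsc = results))
}
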