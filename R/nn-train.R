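# Losses, optimizers, schedulers and the training loop for the
# encoder-decoder models. Parameters travel as nested lists; for the
# optimizer they are flattened to one numeric vector (gradients are
# re-ordered to the parameter order first), which keeps Adam and
# Nesterov-SGD to a few vectorised lines.

# ---- losses ----------------------------------------------------------

bce_eps <- 1e-7

# Sum over (H, W, C) per image b of an (H, W, B, C) array.
per_image_sum <- function(x) {
  d <- dim(x)
  v <- colSums(matrix(x, d[1] * d[2], d[3] * d[4]))
  as.numeric(rowsum(v, rep(seq_len(d[3]), times = d[4])))
}

# Per-image soft Dice with smoothing constant 1; x, t are (H, W, B, C).
soft_dice_terms <- function(pred, target) {
  num <- 2 * per_image_sum(pred * target) + 1
  den <- per_image_sum(pred) + per_image_sum(target) + 1
  list(num = num, den = den, dice = num / den)
}

broadcast_b <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), d)
}

loss_dice <- function(pred, target) {
  d <- dim(pred); B <- d[3]
  t <- soft_dice_terms(pred, target)
  grad <- -(2 * target * broadcast_b(t$den, d) - broadcast_b(t$num, d)) /
    broadcast_b(t$den^2, d) / B
  list(value = mean(1 - t$dice), grad = grad)
}

loss_bce <- function(pred, target) {
  p <- pmin(pmax(pred, bce_eps), 1 - bce_eps)
  m <- length(p)
  list(value = -mean(target * log(p) + (1 - target) * log(1 - p)),
       grad = (p - target) / (p * (1 - p)) / m)
}

# Separable convolution with zero padding (self-adjoint for a symmetric
# kernel, which makes the SSIM gradient exact).
conv_zero <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  mp <- matrix(0, h + 2 * r, w + 2 * r)
  mp[r + seq_len(h), r + seq_len(w)] <- m
  acc <- matrix(0, h, ncol(mp))
  for (i in seq_along(k)) acc <- acc + k[i] * mp[(i - 1L) + seq_len(h), ]
  out <- matrix(0, h, w)
  for (j in seq_along(k)) out <- out + k[j] * acc[, (j - 1L) + seq_len(w)]
  out
}

# SSIM value and d(mean SSIM)/dx for one 2-D slice.
ssim_with_grad <- function(x, y, k, c1, c2) {
  mx <- conv_zero(x, k); my <- conv_zero(y, k)
  vx <- conv_zero(x * x, k) - mx^2
  vy <- conv_zero(y * y, k) - my^2
  cxy <- conv_zero(x * y, k) - mx * my
  a1 <- 2 * mx * my + c1; a2 <- 2 * cxy + c2
  b1 <- mx^2 + my^2 + c1; b2 <- vx + vy + c2
  s <- (a1 * a2) / (b1 * b2)
  n <- length(x)
  ds_dmx <- (2 * my * a2) / (b1 * b2) - (a1 * a2 * 2 * mx) / (b1^2 * b2)
  ds_dvx <- -s / b2
  ds_dcxy <- 2 * a1 / (b1 * b2)
  du <- (ds_dmx - 2 * mx * ds_dvx - my * ds_dcxy) / n
  dv <- ds_dvx / n
  dw <- ds_dcxy / n
  grad <- conv_zero(du, k) + 2 * x * conv_zero(dv, k) + y * conv_zero(dw, k)
  list(value = mean(s), grad = grad)
}

loss_ssim <- function(pred, target, window_size = 11, sigma = 1.5) {
  d <- dim(pred)
  k <- gaussian_kernel(sigma, (window_size - 1) %/% 2)
  c1 <- 0.01^2; c2 <- 0.03^2
  total <- 0
  grad <- array(0, d)
  nslice <- d[3] * d[4]
  for (b in seq_len(d[3])) {
    for (ch in seq_len(d[4])) {
      sg <- ssim_with_grad(pred[, , b, ch], target[, , b, ch], k, c1, c2)
      total <- total + sg$value
      grad[, , b, ch] <- -sg$grad / nslice
    }
  }
  list(value = 1 - total / nslice, grad = grad)
}

nn_loss <- function(loss, pred, target) {
  switch(loss,
    one_minus_dice = loss_dice(pred, target),
    dice_plus_ce = {
      a <- loss_dice(pred, target)
      b <- loss_bce(pred, target)
      list(value = a$value + b$value, grad = a$grad + b$grad)
    },
    one_minus_ssim = loss_ssim(pred, target),
    stop("unknown loss: ", loss)
  )
}

#' Evaluate a training loss
#'
#' `one_minus_dice` is 1 minus the smoothed soft Dice;
#' `dice_plus_ce` adds binary cross-entropy with equal weight;
#' `one_minus_ssim` is 1 minus the mean structural similarity (the
#' minimised form of an SSIM objective). All losses are >= 0 and reach 0
#' (up to the cross-entropy floor) exactly when prediction equals
#' target.
#'
#' @param loss `"one_minus_dice"`, `"dice_plus_ce"` or
#'   `"one_minus_ssim"`.
#' @param pred prediction in \[0,1\]: matrix or (H, W, B, C) array.
#' @param target same shape as `pred`.
#' @return A non-negative scalar.
#' @export
loss_value <- function(loss, pred, target) {
  if (inherits(pred, "rs_scoremap")) pred <- pred$scores
  if (is.matrix(pred)) pred <- array(pred, c(dim(pred), 1, 1))
  if (is.matrix(target)) target <- array(target, c(dim(target), 1, 1))
  if (!identical(dim(pred), dim(target))) stop("prediction/target shape mismatch")
  nn_loss(loss, pred, target)$value
}

# ---- parameter flattening --------------------------------------------

flatten_params <- function(tree) unlist(tree, use.names = FALSE)

# Flatten `tree` in the order of `skel` (gradients are assembled in a
# different member order than the parameters).
flatten_like <- function(skel, tree) {
  if (!is.list(skel)) return(as.numeric(tree))
  nm <- names(skel)
  parts <- lapply(seq_along(skel), function(i) {
    sub <- if (!is.null(nm) && nzchar(nm[i])) tree[[nm[i]]] else tree[[i]]
    flatten_like(skel[[i]], sub)
  })
  unlist(parts, use.names = FALSE)
}

unflatten_into <- function(skel, vec) {
  pos <- 0L
  rec <- function(node) {
    if (!is.list(node)) {
      n <- length(node)
      out <- vec[pos + seq_len(n)]
      pos <<- pos + n
      if (!is.null(dim(node))) dim(out) <- dim(node)
      return(out)
    }
    lapply(node, rec)
  }
  rec(skel)
}

# ---- optimizers ------------------------------------------------------

make_optimizer <- function(name, n, lr) {
  if (name == "adam") {
    state <- list(m = numeric(n), v = numeric(n), t = 0)
    step <- function(p, g, state, lr) {
      state$t <- state$t + 1
      state$m <- 0.9 * state$m + 0.1 * g
      state$v <- 0.999 * state$v + 0.001 * g^2
      mhat <- state$m / (1 - 0.9^state$t)
      vhat <- state$v / (1 - 0.999^state$t)
      list(p = p - lr * mhat / (sqrt(vhat) + 1e-8), state = state)
    }
  } else if (name == "sgd_nesterov") {
    mu <- 0.99
    state <- list(v = numeric(n))
    step <- function(p, g, state, lr) {
      state$v <- mu * state$v - lr * g
      list(p = p + mu * state$v - lr * g, state = state)
    }
  } else stop("unknown optimizer: ", name)
  list(state = state, step = step)
}

scheduler_lr <- function(scheduler, lr0, epoch, epochs, plateau_lr) {
  switch(scheduler,
    none = lr0,
    cosine_annealing = cosine_lr(lr0, epoch, epochs),
    reduce_on_plateau = plateau_lr,
    stop("unknown scheduler: ", scheduler)
  )
}

#' Cosine-annealing learning rate at an epoch checkpoint
#'
#' `lr(e) = eta_min + (lr0 - eta_min) * (1 + cos(pi * (e-1)/(E-1))) / 2`
#' over a single cycle of E epochs; monotone non-increasing within the
#' cycle.
#'
#' @param lr0 initial learning rate.
#' @param epoch 1-based epoch.
#' @param epochs total epochs in the cycle.
#' @param eta_min floor learning rate.
#' @return The learning rate for `epoch`.
#' @export
cosine_lr <- function(lr0, epoch, epochs, eta_min = 0) {
  if (epochs <= 1) return(lr0)
  eta_min + (lr0 - eta_min) * (1 + cos(pi * (epoch - 1) / (epochs - 1))) / 2
}

# ---- training configuration and loop ---------------------------------

#' Training configuration
#'
#' Defaults follow the benchmarked recipes: 100 epochs with the best
#' checkpoint selected by the mean of validation SSIM and validation
#' IoU. Per-model recipes pair `one_minus_dice` with Adam at 0.01 and
#' reduce-on-plateau (segnet_style), `dice_plus_ce` with Nesterov SGD at
#' 0.01 (unet_gn_res), and `one_minus_ssim` with Adam at 1e-4 and
#' cosine annealing (backboned_unet).
#'
#' @param loss see [loss_value()].
#' @param optimizer `"adam"` or `"sgd_nesterov"` (momentum 0.99).
#' @param lr initial learning rate (> 0).
#' @param scheduler `"none"`, `"cosine_annealing"` or
#'   `"reduce_on_plateau"` (factor 0.5, patience 3).
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param seed RNG seed; with the same seed, data order, initial state
#'   and therefore the whole history are reproducible.
#' @return A list of class `rs_train_config`.
#' @export
train_config <- function(loss = "one_minus_dice", optimizer = "adam",
                         lr = 0.01, scheduler = "none", epochs = 100,
                         batch_size = 8, seed = 1) {
  if (lr <= 0) stop("lr must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(loss = loss, optimizer = optimizer, lr = lr,
                 scheduler = scheduler, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = seed,
                 selection_metric = "mean(val SSIM, val IoU)"),
            class = "rs_train_config")
}

batch_tensor <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, c(d[1], d[2], length(images), d[3]))
  for (i in seq_along(images)) x[, , i, ] <- images[[i]]
  x
}

target_tensor <- function(masks, out_channels) {
  d <- dim(masks[[1]])
  t <- array(0, c(d[1], d[2], length(masks), out_channels))
  for (i in seq_along(masks)) {
    t[, , i, 1] <- masks[[i]]
    if (out_channels == 2) t[, , i, 2] <- 1 - masks[[i]]
  }
  t
}

# Validation-set SSIM (raw scores vs mask, clipped to [0,1]) and
# smoothed IoU of the 0.5-binarised prediction.
validate_model <- function(model, val) {
  ss <- numeric(nrow(val)); jj <- numeric(nrow(val))
  for (i in seq_len(nrow(val))) {
    sm <- predict(model, val$image[[i]])$scores
    ss[i] <- min(max(ssim_index(sm, val$mask[[i]])), 1)
    ss[i] <- max(ss[i], 0)
    jj[i] <- iou(binarize(sm, 0.5), val$mask[[i]])
  }
  c(ssim = mean(ss), iou = mean(jj))
}

#' Train an encoder-decoder model
#'
#' Runs `cfg$epochs` epochs of minibatch gradient descent on the train
#' split, logging train loss, validation SSIM, validation IoU and the
#' learning rate after every epoch, and returns the checkpoint with the
#' highest mean of validation SSIM and IoU. Fully reproducible under
#' `cfg$seed`.
#'
#' @param model an `rs_nn_model` from [build_model()].
#' @param data an `rs_bundle` with a `split` column containing `train`
#'   and `val` rows.
#' @param cfg an [train_config()].
#' @return A list of class `rs_trained` with `model` (best checkpoint),
#'   `history` (tibble, one row per epoch), `best_epoch`, `config`.
#' @export
train_model <- function(model, data, cfg = train_config()) {
  if (!"split" %in% names(data)) stop("data bundle carries no split labels")
  tr <- data[data$split == "train", ]
  va <- data[data$split == "val", ]
  if (nrow(tr) == 0 || nrow(va) == 0) stop("train and val splits must be non-empty")
  oc <- model$spec$out_channels
  p <- flatten_params(model$params)
  opt <- make_optimizer(cfg$optimizer, length(p), cfg$lr)
  opt_state <- opt$state
  history <- vector("list", cfg$epochs)
  best_score <- -Inf; best_p <- p; best_epoch <- 0L
  plateau_lr <- cfg$lr; plateau_wait <- 0L; plateau_best <- -Inf
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- scheduler_lr(cfg$scheduler, cfg$lr, epoch, cfg$epochs, plateau_lr)
    ord <- sample(nrow(tr))
    losses <- c()
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      x <- batch_tensor(tr$image[idx])
      t <- target_tensor(tr$mask[idx], oc)
      model$params <- unflatten_into(model$params, p)
      fw <- nn_forward(model, x)
      ls <- nn_loss(cfg$loss, fw$out, t)
      if (!is.finite(ls$value)) {
        stop(sprintf("training diverged: non-finite %s loss at epoch %d",
                     cfg$loss, epoch))
      }
      losses <- c(losses, ls$value)
      grads <- nn_backward(model, fw$cache, ls$grad)
      g <- flatten_like(model$params, grads)
      stepped <- opt$step(p, g, opt_state, lr)
      p <- stepped$p; opt_state <- stepped$state
    }
    model$params <- unflatten_into(model$params, p)
    vm <- validate_model(model, va)
    sel <- mean(vm)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = mean(losses),
      val_ssim = vm[["ssim"]], val_iou = vm[["iou"]], selection = sel)
    if (sel > best_score) {
      best_score <- sel; best_p <- p; best_epoch <- epoch
    }
    if (cfg$scheduler == "reduce_on_plateau") {
      if (sel > plateau_best + 1e-6) {
        plateau_best <- sel; plateau_wait <- 0L
      } else {
        plateau_wait <- plateau_wait + 1L
        if (plateau_wait >= 3L) {
          plateau_lr <- plateau_lr * 0.5
          plateau_wait <- 0L
        }
      }
    }
  }
  model$params <- unflatten_into(model$params, best_p)
  structure(list(model = model, history = dplyr::bind_rows(history),
                 best_epoch = best_epoch, best_score = best_score,
                 config = cfg),
            class = "rs_trained")
}

#' @export
print.rs_trained <- function(x, ...) {
  cat(sprintf("<rs_trained %s> %d epochs, best epoch %d (selection %.4f)\n",
              x$model$spec$family, nrow(x$history), x$best_epoch,
              x$best_score))
  invisible(x)
}

#' Predict with a trained model
#'
#' @param object an `rs_trained`.
#' @param newdata an image array or [rs_pair].
#' @param ... passed to the model's predict method.
#' @return An `rs_scoremap`.
#' @export
predict.rs_trained <- function(object, newdata, ...) {
  img <- if (inherits(newdata, "rs_pair")) newdata$image else newdata
  predict(object$model, img, ...)
}
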