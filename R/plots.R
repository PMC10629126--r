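# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_point
#'   geom_col geom_ribbon labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object an `rs_roc`.
#' @param ... unused.
#' @return A ggplot: TPR vs FPR with the chance diagonal dashed.
#' @export
autoplot.rs_roc <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    geom_line(colour = "#2c7fb8") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("Pixel-pooled ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' Plot a predicted-vs-labelled length regression
#'
#' @param object an `rs_regression`.
#' @param ... unused.
#' @return A ggplot: scatter with the OLS line and its 95% confidence
#'   ribbon.
#' @export
autoplot.rs_regression <- function(object, ...) {
  rec <- object$records
  grid <- data.frame(labelled_mm = seq(min(rec$labelled_mm),
                                       max(rec$labelled_mm),
                                       length.out = 100))
  pr <- predict(object$fit, grid, interval = "confidence")
  grid$fit <- pr[, "fit"]; grid$lwr <- pr[, "lwr"]; grid$upr <- pr[, "upr"]
  ggplot(rec, aes(x = .data$labelled_mm, y = .data$predicted_mm)) +
    geom_ribbon(data = grid, aes(x = .data$labelled_mm, y = .data$fit,
                                 ymin = .data$lwr, ymax = .data$upr),
                fill = "grey80", alpha = 0.6) +
    geom_line(data = grid, aes(y = .data$fit), colour = "#2c7fb8") +
    geom_point(alpha = 0.7) +
    labs(x = "Labelled root length (mm)", y = "Predicted root length (mm)",
         title = sprintf("predicted = %.2f x labelled %+.2f,  R² = %.3f",
                         object$slope, object$intercept, object$r2)) +
    theme_minimal()
}

#' Plot a training history
#'
#' @param trained an `rs_trained` (or its history tibble).
#' @return A ggplot of train loss and validation metrics per epoch.
#' @export
plot_training_history <- function(trained) {
  h <- if (inherits(trained, "rs_trained")) trained$history else trained
  long <- tidyr_longer(h)
  ggplot(long, aes(x = .data$epoch, y = .data$value)) +
    geom_line(colour = "#2c7fb8") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "Epoch", y = NULL) +
    theme_minimal()
}

# tiny local pivot to avoid a tidyr dependency for one call
tidyr_longer <- function(h) {
  metrics <- c("train_loss", "val_ssim", "val_iou", "lr")
  dplyr::bind_rows(lapply(metrics, function(m) {
    tibble::tibble(epoch = h$epoch, metric = m, value = h[[m]])
  }))
}

#' Bar chart of a benchmark report
#'
#' @param object an `rs_report`.
#' @param split which split to show (`"test"` or `"val"`).
#' @param ... unused.
#' @return A ggplot of mean SSIM/DSC/IoU per method.
#' @export
autoplot.rs_report <- function(object, split = "test", ...) {
  tab <- object$metrics[object$metrics$split == split, ]
  long <- dplyr::bind_rows(lapply(c("mean_ssim", "mean_dsc", "mean_iou"),
    function(m) tibble::tibble(method = tab$method, metric = m,
                               value = tab[[m]])))
  ggplot(long, aes(x = .data$method, y = .data$value)) +
    geom_col(fill = "#2c7fb8") +
    facet_wrap(~metric) +
    labs(x = NULL, y = NULL, title = paste("Benchmark metrics,", split,
                                           "split")) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom rlang .data
NULL
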