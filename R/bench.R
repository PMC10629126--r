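# End-to-end orchestration: generate -> prepare -> tune/train ->
# evaluate -> report, emitting per-method metric rows (validation and
# test), ROC data, and predicted-vs-labelled length regressions.

#' Benchmark run configuration
#'
#' Assembles (and validates) the full run description. Any part can be
#' overridden; defaults give a small, CPU-friendly run.
#'
#' @param generator list: `n`, `soil_fraction`, `image_size`, `domains`
#'   (names from [synth_domains()]), `pixel_scale`, `seed`.
#' @param mix optional named proportions over `generator$domains`; when
#'   given, per-domain pools are generated and mixed with
#'   [mix_datasets()].
#' @param split list: `test_ratio`, `val_ratio`, `seed`.
#' @param standardize_size working image side in px.
#' @param methods list of method entries, each a list with `name` in
#'   `dummy|frangi|adaptive|svm|segnet_style|unet_gn_res|backboned_unet`,
#'   optional `augmented` flag and per-method settings (`epochs`,
#'   `base_width`, `depth`, `n_trials`, ...).
#' @param augment list passed to [augment_policy()].
#' @param threshold score binarisation level for mask metrics.
#' @param out_dir optional output directory for CSV/JSON artefacts.
#' @return A list of class `rs_run_config`.
#' @export
run_config <- function(generator = list(), mix = NULL, split = list(),
                       standardize_size = 64,
                       methods = list(list(name = "dummy")),
                       augment = list(), threshold = 0.5, out_dir = NULL) {
  gen <- modifyList(list(n = 60, soil_fraction = 0.3, image_size = c(64, 64),
                         domains = c("sandy_red", "loess", "dark_wet"),
                         pixel_scale = 0.1, seed = 1, n_roots_lambda = 2,
                         root_width_range = c(2, 5), artefact_density = 2,
                         scratch_density = 0.3), generator)
  spl <- modifyList(list(test_ratio = 0.1, val_ratio = 0.1, seed = 1), split)
  known <- c("dummy", "frangi", "adaptive", "svm", "segnet_style",
             "unet_gn_res", "backboned_unet")
  for (m in methods) {
    if (!m$name %in% known) stop("unregistered method: ", m$name)
  }
  if (!is.null(mix) && abs(sum(unlist(mix)) - 1) > 1e-9) {
    stop("mix proportions must sum to 1")
  }
  structure(list(generator = gen, mix = mix, split = spl,
                 standardize_size = standardize_size, methods = methods,
                 augment = augment, threshold = threshold,
                 out_dir = out_dir),
            class = "rs_run_config")
}

method_label <- function(m) {
  paste0(m$name, if (isTRUE(m$augmented)) " + aug" else "")
}

generate_from_config <- function(cfg) {
  gen <- cfg$generator
  recipes <- lapply(gen$domains, function(d) {
    scene_recipe(image_size = gen$image_size, domain = d,
                 n_roots_lambda = gen$n_roots_lambda,
                 root_width_range = gen$root_width_range,
                 artefact_density = gen$artefact_density,
                 scratch_density = gen$scratch_density,
                 pixel_scale = gen$pixel_scale)
  })
  if (is.null(cfg$mix)) {
    generate_dataset(recipes, n = gen$n, soil_fraction = gen$soil_fraction,
                     seed = gen$seed)
  } else {
    names(recipes) <- gen$domains
    pools <- lapply(seq_along(recipes), function(i) {
      generate_dataset(recipes[[i]], n = ceiling(gen$n * 1.2),
                       soil_fraction = gen$soil_fraction,
                       seed = derive_seed(gen$seed, 1000 + i))
    })
    names(pools) <- gen$domains
    mix_datasets(pools, cfg$mix, total = gen$n, seed = gen$seed)
  }
}

# Fit (where needed) and predict score maps for one method entry.
run_method <- function(m, train, val, predict_on, cfg) {
  predict_all <- function(fun) lapply(predict_on$image, fun)
  switch(m$name,
    dummy = predict_all(function(img) dummy_segment(img)$scores),
    frangi = {
      params <- frangi_params(scales = m$scales %||% c(1, 2, 3),
                              beta = m$beta %||% 0.5)
      predict_all(function(img) frangi_segment(img, params)$scores)
    },
    adaptive = {
      grid <- if (!is.null(m$grid)) m$grid else
        expand.grid(block_size = seq(11, 31, by = 8),
                    offset = seq(0, 0.08, by = 0.02),
                    weighting = "gaussian", stringsAsFactors = FALSE)
      best <- tune_adaptive(grid, val)
      predict_all(function(img) adaptive_threshold(img, best)$scores)
    },
    svm = {
      scfg <- svm_config(n_trials = m$n_trials %||% 8,
                         pixel_subsample = m$pixel_subsample %||% 500,
                         seed = m$seed %||% 1)
      found <- svm_random_search(train, val, scfg)
      predict_all(function(img) predict_svm(found$classifier, img)$scores)
    },
    {
      spec <- model_spec(family = m$name, base_width = m$base_width %||% 8,
                         depth = m$depth %||% 3,
                         out_channels = m$out_channels %||%
                           (if (m$name == "unet_gn_res") 2 else 1),
                         seed = m$seed %||% 1)
      defaults <- switch(m$name,
        segnet_style = list(loss = "one_minus_dice", optimizer = "adam",
                            lr = 0.01, scheduler = "reduce_on_plateau"),
        unet_gn_res = list(loss = "dice_plus_ce", optimizer = "sgd_nesterov",
                           lr = 0.01, scheduler = "none"),
        backboned_unet = list(loss = "one_minus_ssim", optimizer = "adam",
                              lr = 1e-4, scheduler = "cosine_annealing"))
      tc <- train_config(loss = m$loss %||% defaults$loss,
                         optimizer = m$optimizer %||% defaults$optimizer,
                         lr = m$lr %||% defaults$lr,
                         scheduler = m$scheduler %||% defaults$scheduler,
                         epochs = m$epochs %||% 10,
                         batch_size = m$batch_size %||% 8,
                         seed = m$seed %||% 1)
      data <- dplyr::bind_rows(train, val)
      model <- build_model(spec)
      fit <- train_model(model, data, tc)
      predict_all(function(img) predict(fit, img)$scores)
    }
  )
}

#' Run the full benchmark described by a configuration
#'
#' For every requested method (optionally duplicated "+ aug" with the
#' fourfold-augmented training set) the pipeline generates the synthetic
#' dataset, standardizes and splits it, fits or tunes the method,
#' evaluates metric rows on the validation and test splits, computes
#' pooled ROC curves and predicted-vs-labelled length regressions on the
#' test split, and (when `out_dir` is set) persists CSV/JSON artefacts
#' plus a provenance log. Deterministic under the config's seeds.
#'
#' @param cfg an [run_config()].
#' @return A list of class `rs_report`: `metrics` (tibble with a `split`
#'   column), `lengths`, `regressions`, `bundle_summary`, `config`.
#' @export
run_benchmark <- function(cfg) {
  stage <- "generate"
  result <- tryCatch({
    bundle <- generate_from_config(cfg)
    stage <- "prepare"
    bundle <- standardize_bundle(bundle, cfg$standardize_size)
    bundle <- recurrent_split(bundle, split_spec(cfg$split$test_ratio,
                                                 cfg$split$val_ratio,
                                                 cfg$split$seed))
    tr <- as_rs_bundle(bundle[bundle$split == "train", ])
    va <- as_rs_bundle(bundle[bundle$split == "val", ])
    te <- as_rs_bundle(bundle[bundle$split == "test", ])
    policy <- do.call(augment_policy, cfg$augment)
    tr_aug <- NULL
    metrics <- list(); lengths <- list(); regressions <- list()
    for (m in cfg$methods) {
      stage <- paste0("method:", m$name)
      if (isTRUE(m$augmented) && is.null(tr_aug)) {
        tr_aug <- augment_bundle(tr, policy)
      }
      use_train <- if (isTRUE(m$augmented)) tr_aug else tr
      label <- method_label(m)
      for (split_name in c("val", "test")) {
        target <- if (split_name == "val") va else te
        scores <- run_method(m, use_train, va, target, cfg)
        row <- evaluate_method(scores, target, method = label,
                               threshold = cfg$threshold)
        row$split <- split_name
        metrics[[paste(label, split_name)]] <- row
        if (split_name == "test") {
          preds <- lapply(scores, binarize, threshold = cfg$threshold)
          lr <- length_records(preds, target)
          lr$method <- label
          lengths[[label]] <- lr
          regressions[[label]] <- tryCatch(length_regression(lr),
                                           error = function(e) NULL)
        }
      }
    }
    metrics <- dplyr::bind_rows(metrics)
    report <- structure(list(
      metrics = metrics,
      lengths = dplyr::bind_rows(lengths),
      regressions = regressions,
      bundle_summary = list(n = nrow(bundle),
                            n_soil_only = sum(bundle$soil_only),
                            splits = table(bundle$split),
                            composition = bundle_composition(bundle)),
      config = cfg), class = "rs_report")
    if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
    report
  }, error = function(e) {
    stop(sprintf("benchmark failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

#' Persist a benchmark report
#'
#' Writes `report.csv` (metric rows in table column order), per-method
#' ROC curves, the length table, regression summaries and a provenance
#' log.
#'
#' @param report an `rs_report`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- report$metrics
  for (i in seq_len(nrow(tab))) {
    r <- tab$roc[[i]]
    if (!is.null(r)) {
      fn <- sprintf("roc_%s_%s.csv", gsub("[^a-z0-9]+", "_", tab$method[i]),
                    tab$split[i])
      write.csv(r$curve, file.path(dir, fn), row.names = FALSE)
    }
  }
  out <- tab[, c("split", "method", "mean_ssim", "mean_dsc", "mean_iou",
                 "fpr", "fpr_excluded", "n_images", "n_soil_only")]
  write.csv(out, file.path(dir, "report.csv"), row.names = FALSE)
  if (nrow(report$lengths) > 0) {
    write.csv(report$lengths, file.path(dir, "lengths.csv"), row.names = FALSE)
  }
  regs <- report$regressions[!vapply(report$regressions, is.null, TRUE)]
  if (length(regs) > 0) {
    jsonlite::write_json(lapply(regs, function(r) {
      list(slope = r$slope, intercept = r$intercept, r2 = r$r2,
           ci95_slope = r$ci95_slope, ci95_intercept = r$ci95_intercept,
           n = r$n)
    }), file.path(dir, "regressions.json"), auto_unbox = TRUE, digits = NA)
  }
  prov <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    r_version = as.character(getRversion()),
    generator_seed = report$config$generator$seed,
    split_seed = report$config$split$seed,
    n_images = report$bundle_summary$n,
    methods = vapply(report$config$methods, method_label, "")
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.rs_report <- function(x, ...) {
  cat("<rs_report>\n")
  print(x$metrics[, c("split", "method", "mean_ssim", "mean_dsc",
                      "mean_iou", "fpr")])
  invisible(x)
}
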