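Package: rootsegbench
Title: Benchmarking Semantic Segmentation of Roots in Minirhizotron Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale benchmarking pipeline for root segmentation in
    minirhizotron images. Generates reproducible synthetic image/mask pairs
    with known centerline root length on heterogeneous soil backgrounds;
    prepares datasets by tiling, rescaling and recurrent 1:9 splitting with
    proportioned mixing; applies fourfold flip augmentation with photometric
    jitter; runs six segmentation methods (majority-class dummy baseline,
    Frangi vesselness on a bilateral-filtered green-minus-blue channel,
    locally adaptive thresholding tuned by validation Dice, a pixel-wise
    colour SVM, and small encoder-decoder networks trained with Dice,
    Dice-plus-cross-entropy or SSIM losses); evaluates them with smoothed
    Dice and Jaccard overlap, the structural similarity index, image-level
    false positive rate on soil-only images and pixel-pooled ROC curves; and
    converts predicted masks to total root length by skeletonisation with a
    linear regression report against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
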