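---
title: "Methods: benchmarking root segmentation on synthetic minirhizotron scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking root segmentation on synthetic minirhizotron scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## What the synthetic generator emulates — and what it does not

Real minirhizotron campaigns differ by device and site: soil colour and
texture, illumination uniformity, focus, and the density of bright
confounders (small stones, water droplets, scratched foil). The
generator reproduces exactly those axes:

* **Soil background** = a low-frequency multiplicative illumination
  field (bilinearly interpolated 4×4 gain grid plus a random linear
  gradient) times high-frequency Gaussian speckle, in a per-domain
  colour palette. Four built-in domains (`synth_domains()`) span a
  sharp bright sandy soil, a mildly blurred loess, a dark heavily
  shadowed wet soil, and a potting-mix domain with *dark* roots —
  bright-on-dark is the default polarity.
* **Roots** are smooth random-walk polylines (step 2.5 px, angular
  increments N(0, 0.12)) entering from an image edge, rasterised as
  tubes of slowly varying radius; the mask is the union of those tubes
  and the ground-truth length is the exact polyline arc length times
  the mm/px scale. Root colour keeps G ≥ B so the vesselness
  preprocessing has the contrast it assumes.
* **Artefacts** — bright ellipses (stones/droplets) and thin
  high-contrast line segments (scratches) — are drawn *after* the
  roots, on the image only, never in the mask. They are the confounders
  that defeat intensity thresholding.
* **Soil-only images**: `generate_dataset(n, soil_fraction)` forces
  exactly `round(n * soil_fraction)` scenes to contain no roots. The
  default fraction is 0.30, the share the mixed benchmark set carries.
* **Determinism**: every image's RNG stream is a hash of
  (master seed, image index), so bundles regenerate byte-identically
  and single images can be re-rendered in isolation.

No quantitative description of artefact frequency or per-image root
coverage exists for the real campaigns, so the default densities
(roots ~Pois(2), stones ~Pois(3), scratches ~Pois(0.5) per image) were
chosen once as visually plausible for field imagery and are not
calibrated values. The generator does not attempt photorealism, root
growth over time, or multispectral channels. Consequently, passing
tests demonstrate that the *methodology* behaves as specified — metric
arithmetic, training dynamics, the ranking of a learning method over a
no-information baseline — not that any method will attain a particular
score on real images.

## Dataset preparation

* **Tiling.** `tile_grid(pair, n)` maps the requested count to the
  rows×cols factorisation whose tiles are closest to square for that
  image (64 → 8×8 on a 2550×2273 capture; 32 → a 4×8-shaped grid on a
  3991×1842 one); trailing remainder pixels are cropped and the
  soil-only flag is recomputed per tile. `tile_overlapping(pair, size,
  n)` picks the grid minimising uncovered area, spaces origins evenly
  (equal overlaps when the grid span exceeds the image, symmetric
  margins when it falls short), and always returns tiles of exactly the
  requested size. Coordinates are row-major, origin top-left, tiles
  half-open.
* **Rescaling.** Bilinear for images, nearest-neighbour + 0.5 threshold
  for masks, so masks stay strictly binary; the mm/px scale is
  multiplied by the mean of the two axis resize factors.
* **Recurrent splitting.** First test vs. the rest at ratio 0.1, then
  validation vs. training at 0.1 of the remainder, both rounded half
  away from zero. For 687 images this yields 69 / 62 / 556. A published
  table of the same procedure prints training = 557 with the identical
  69 and 62 — internally inconsistent with its own total of 687 — so
  the package follows the stated rule and documents the one-image
  discrepancy rather than matching the printed 557.
* **Mixing.** Per-source counts are `round(total × fraction)` with any
  rounding remainder assigned to the largest fraction; sampling is
  without replacement and shortages fail loudly naming the source.

## Augmentation

`expand_fourfold()` returns exactly `[original, h-flip, v-flip,
channel-flip]` — the ×4 count is structural, photometric jitter rides
on top of the three flipped copies rather than forming extra ones. Each
of Gaussian blur, vertical motion blur, brighten and darken is applied
independently with probability 0.5 per copy; brightness steps clip to
[0,1] immediately (sensor-style saturation). "Flipping the RGB channel"
is read as reversing channel order (RGB→BGR); the source description is
ambiguous between reversal and a random permutation, and reversal is
the simplest deterministic reading. Masks are never touched by
photometric transforms and are flipped pixel-for-pixel by the geometric
ones.

## Classical segmenters

* **Dummy**: all-zero scores — the majority class. Its smoothed-metric
  signatures (below) anchor the reports.
* **Frangi vesselness** runs on a preprocessed channel: bilateral
  filter (spatial σ 3 px, range σ 0.1) per channel, then G−B, rescaled
  to [0,1]. Defaults: scales {1,2,3,4} px, β = 0.5, bright-ridge
  polarity, and structureness weight c chosen adaptively per image and
  scale as half the maximum Hessian Frobenius norm — standard choices
  for the filter family; the benchmark source prints none. Gaussian
  second-derivative kernels are made exactly DC-free (`g2 − mean(g2)`)
  so constant images give a strictly zero Hessian; when an image is
  flat at some scale (max norm < 1e−10) that scale contributes nothing
  rather than amplifying float noise through the adaptive c.
* **Adaptive thresholding** marks a pixel as root iff its luminance
  (ITU-R 601 weights) exceeds the local window mean by more than
  `offset`. The "exceeds by offset" direction is the one consistent
  with a constant image yielding an empty mask for positive offsets —
  the bright-object reading. The Gaussian window uses the conventional
  `0.3·((b−1)/2 − 1) + 0.8` sigma. Tuning is an exhaustive grid search
  (block sizes 11–51 step 4, offsets 0–0.10 step 0.01) maximising mean
  validation DSC, ties broken by smaller block then smaller offset.
* **Pixel SVM**: each image flattens to an (H·W)×3 RGB feature matrix;
  fitting uses a balanced subsample of ≤ 2000 px per image. The random
  search (100 trials by default) draws kernel ∈ {linear, RBF}, C
  log-uniform in [1e−2, 1e2], γ log-uniform in [0.1, 10] and a solver
  effort level from {1e3, 1e4, 1e5}. The underlying quadratic-program
  solver is tolerance-bounded, not iteration-bounded, so the effort
  level maps onto its convergence tolerance (10/effort, capped at 0.1).

## Encoder–decoder models and training

The three families share one small convolution engine (im2col gathers
in C++, BLAS matrix products, hand-written backward passes verified
against finite differences in the test suite):

* `segnet_style`: conv blocks with 2×2 max-pooling that records argmax
  indices; the decoder reduces channels at the coarse resolution and
  scatters features back through max-unpooling. No skip connections.
* `unet_gn_res`: U-Net skips plus residual blocks with group
  normalisation (groups of ~4 channels; GN behaves identically at any
  batch size, which is why it replaces batch norm here) and a
  two-channel head trained toward the mask and its negative.
  `predict_padded()` implements the 324→260→256 geometry: reflect-pad
  the 256×256 input to 324, crop the model output to 260, centre-crop
  to 256 for evaluation, so padding never enters the metrics.
* `backboned_unet`: a plain U-Net behind a pluggable encoder interface;
  only the "tiny" encoder ships. Heavyweight pretrained backbones would
  plug in behind the same interface but are out of scope — they need a
  GPU and external weights.

Capacity defaults are deliberately tiny (depth 3, width 8): the point
is a CPU-sized, fully testable replica of the training contracts, not
ImageNet-grade capacity.

Losses: `one_minus_dice` (soft Dice, smoothing constant 1 — the same
constant as the metrics, so train and test speak the same language),
`dice_plus_ce` (equal weights), and `one_minus_ssim` (11-tap Gaussian
window, σ 1.5; the loss convolutions use zero padding, which makes the
analytic gradient exact because the symmetric kernel is then
self-adjoint — the *metric* SSIM uses reflective padding, which is the
better estimator at borders). Optimizers: Adam (0.9/0.999) and Nesterov
SGD with momentum 0.99 — the momentum the residual-U-Net lineage uses;
it is not printed in the benchmark source. Schedulers: none, cosine
annealing over a single cycle (`lr(e) = lr₀(1 + cos(π(e−1)/(E−1)))/2`,
asserted against this closed form in the tests), and reduce-on-plateau
(factor 0.5, patience 3 on the selection metric). Model selection is
the arithmetic mean of validation SSIM and validation IoU after each
epoch — "combination" without a printed formula is read as the
equal-weight mean, which preserves ordering for any equal weighting.
Training aborts with a diagnostic on non-finite loss, and the whole
loop is bit-reproducible under the config seed.

## Evaluation layer

* **Smoothing rationale.** With additive constant 1, an all-zero
  prediction scores DSC = IoU = 1/(|B|+1) > 0 and empty-vs-empty scores
  1. These two conventions jointly force the dummy-row behaviour the
  benchmark tables show: equal, small, non-zero DSC/IoU on a rootless
  prediction (1/311 ≈ 0.0032 against a 310-px mask), and means ≈ the
  soil-only fraction on mixed sets. The bare coefficients remain
  available via `smooth = 0`.
* **SSIM** treats masks as real-valued images with dynamic range 1
  (window 11, σ 1.5, K₁ = 0.01, K₂ = 0.03); the reported per-image
  value is the windowed mean, clipped to [0,1] in aggregates. Whether
  the original evaluation used masks or probability maps is unstated;
  masks are the choice here because every method, thresholded, produces
  one.
* **FPR** counts an image as a false positive at ≥ 1 predicted root
  pixel (a configurable `min_area` exists but defaults to 1 — the
  strictest reading of "classified as containing roots"). Methods that
  predict no roots anywhere are excluded, mirroring the tables'
  footnote, because an FPR of 0 earned by never predicting would be
  meaningless.
* **ROC** pools all pixels of all images and sweeps 256 evenly spaced
  thresholds with a leading anchor at (0,0); AUC is trapezoidal.
  Constant scores give the diagonal and AUC 0.5 exactly.

## Root length

Masks are thinned with Zhang–Suen iterative thinning (1-px-wide,
8-connected, topology-preserving, always a subset of the mask) and
length is skeleton pixel count × mm/px. That estimator under-measures
diagonal roots by up to √2 — an orientation bias the tests assert on a
45° tube rather than hide; the √2-weighted link-count variant is
provided (`diagonal_weighted = TRUE`) but is not the default, because
fidelity to the benchmarked estimator comes first. Bar ends also erode
by a pixel or two during thinning (reference thinning gives 97 on a
100×5 bar), which is why length recovery is asserted at the 5% level,
not exactly. The predicted-vs-labelled regression is OLS with
intercept; R² and t-based 95% intervals come from the standard linear
model machinery, exposed via `tidy()`/`glance()`.

## Problem sizes and numerical choices

The test suite and acceptance script run everything at desk scale,
chosen as the smallest sizes at which each property is meaningfully
exercised: 48–128 px synthetic scenes for module tests; the counting
claims at their true dimensions (65 × 2550×2273, 48 × 3991×1842,
25 × 2592×2944 stand-ins); ROC anchors at 10⁶ pooled pixels; the
regression study at n = 200; and the training study on 200 synthetic
64×64 pairs for 20 epochs with the depth-3 width-8 U-Net, which beats
the dummy baseline's mean DSC by a wide margin (the suite requires
≥ 0.2). Reported reproducibility is bitwise: hashes of (seed, index)
drive every stochastic stage.

Degenerate inputs fail loudly by design: empty bundles, single-class
SVM labels, zero-variance regressions, even adaptive block sizes,
soil-only recipes passed to the trace sampler, undefined unsmoothed
metrics on empty masks, and single-class pooled ROC truth all raise
typed errors rather than returning numbers.

## Known limitations

Synthetic soil is statistically textured, not photorealistic; domain
shift between the built-in domains is milder than between real imaging
campaigns. The tiny encoders cannot represent the capacity effects that
separate large pretrained backbones from small ones, so cross-family
rankings here reflect architecture class and training recipe, not
published leaderboard order. Root-length ground truth is exact for the
generator's polylines, which have no branching hierarchy or overlap
crossings; real annotated masks carry annotator bias the generator does
not model.
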