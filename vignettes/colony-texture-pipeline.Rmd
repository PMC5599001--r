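---
title: "Orderless texture pooling for bacterial micrograph classification"
author: "bactex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orderless texture pooling for bacterial micrograph classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Different bacterial genera and species reproduce in characteristic ways:
cocci, rods and curved rods appear solitary, in chains, or in clusters, at
different sizes and densities. In a Gram-stained micrograph this shows up as
*texture* — a statistical signature of local structure rather than any single
object — which is why orderless texture representations are a natural fit for
species-level classification of such images.

`bactex` implements the full pipeline:

1. **Local descriptors.** Dense SIFT: at every point of a regular grid
   (default step 2 px) a patch of side `4 * bin_size` is described by a
   histogram of image gradients, quantized into 4 × 4 spatial bins and 8
   orientation bins, giving a 128-dimensional descriptor. Alternatively, any
   registered *backend* can supply a field of deep local descriptors (the
   analogue of truncating a convolutional network at its last conv layer) and
   a global penultimate-layer vector ("FC").
2. **Pooling encoder.** A diagonal-covariance Gaussian mixture model (GMM)
   with `K` components is fitted to (optionally PCA-projected) training
   descriptors by EM. An image's descriptors are softly assigned to
   components, and for each component `k` the first-order statistic
   $u_k = \frac{1}{N\sqrt{w_k}} \sum_i \gamma_{ik} \frac{x_i - \mu_k}{\sigma_k}$
   and second-order statistic
   $v_k = \frac{1}{N\sqrt{2 w_k}} \sum_i \gamma_{ik}\!\left(\frac{(x_i - \mu_k)^2}{\sigma_k^2} - 1\right)$
   are pooled. Concatenating all $u_k$ then all $v_k$ gives the Fisher
   Vector of length $2Kd$. Zeroth-order (weight-gradient) terms are excluded:
   the representation uses first- and second-order statistics only.
3. **Classifier.** The reference classifier ("original") is a one-vs-all
   linear SVM with C = 1. One-vs-one SVMs with linear, polynomial or RBF
   kernels tune their hyperparameters by Bayesian optimization of 5-fold
   stratified cross-validated accuracy; a boosted-tree ensemble
   ("rf-adaboost", multiclass AdaBoost/SAMME over depth-limited trees) covers
   the ensemble family.

Representations are named `X-Y` (pooling encoder, then descriptor):
`FV-SIFT`, `FV-toy`, `FC-toy`; `FCFV-toy` abbreviates `FC-toy & FV-toy`, and
`" & "` concatenates independently L2-normalized blocks followed by a global
L2 normalization.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `step` | 2 px | dense sampling step; 2 px gives near-pixel-dense coverage |
| `bin_size` | 8 px | SIFT spatial bin; patch side is 32 px, a scale that spans one to a few bacterial cells at typical magnifications |
| `gmm_k` | 64 | GMM components; more components give a finer partition of descriptor space at linear cost in time and representation size |
| `pca_dim` | 64 | PCA projection of SIFT descriptors before the GMM; decorrelates dimensions (the diagonal-covariance assumption) and reduces EM cost |
| `pca_dim_conv` | 0 (off) | deep conv descriptors are already low-dimensional in the toy backend |
| `fv_norm` | `ssr_l2` | signed square root then global L2 (the improved-FV convention); `ssr` and `none` are available for analysis |
| `subsample` | 100000 | pooled training descriptors used to fit PCA/GMM; beyond this the fit no longer changes materially |
| `C` | 1 | soft-margin cost of the reference one-vs-all linear SVM |
| optimizer box | `log10 C ∈ [-3, 3]`, `log10 γ ∈ [-4, 1]`, degree 2–4 | search space for the Bayes-optimized SVMs; budget 25 evaluations |

All representation blocks are standardized (training-set mean/variance)
before SVM fitting; FV normalization alone leaves scale differences between
concatenated blocks, and the scaler is stored with each model.

## Numerical choices

- **SIFT geometry.** Gradients are central differences, so adding a constant
  intensity changes nothing; L2 normalization makes descriptors invariant to
  positive intensity scaling. Components are clamped at 0.2 after the first
  L2 normalization and renormalized (the standard burstiness guard); flat
  patches return the all-zero descriptor rather than NaN. Patches must fit
  entirely inside the image (margin `2 * bin_size`, no padding), so on an
  H-pixel side the grid has `floor((H - 1 - 4*bin_size)/step) + 1` centers.
- **EM.** Seeded k-means initialization; per-dimension variance floor of
  `1e-4` times the data variance; stop at relative log-likelihood improvement
  `< 1e-6` or 200 iterations. The log-likelihood trace is non-decreasing (an
  EM guarantee the test suite asserts to 1e-9). A component whose weight
  collapses below 1e-8 is re-seeded at a random data point once; a second
  collapse is an error.
- **Soft assignment** is computed in the log domain (log-sum-exp), so
  posteriors sum to one to 1e-10 even for far-out descriptors. Inside the
  encoder, posteriors below 1e-8 are truncated to zero for speed
  (`posterior_floor = 0` disables this).
- **Ties.** Multiclass decisions break toward the lowest class ID in
  numeric major.minor order ("2.1" before "10.2").
- **Seeding.** Every stochastic stage takes a seed; a master seed fans out
  deterministically (`derive_seed`) to splits, subsampling, EM, optimizers
  and the generator, so every evaluation is bit-reproducible and report JSON
  files are byte-identical across reruns. Split sub-seeds are
  `seed + class position`, so adding a class leaves other classes' splits
  unchanged.

## Evaluation protocols

**Repeated equal split.** Each class is split into equal disjoint train/test
halves (default 10/10, matching a 33-species × 20-image collection: 330
training and 330 test images). Per repeat, the encoder is fitted on training
descriptors only and a fresh classifier is trained; accuracy is the fraction
of correctly classified test images (micro-average), reported as mean ± sd
over repeats (default 25). The confusion matrix accumulates over repeats
with entry (i, j) counting observations of true class i predicted as class
j, so row i sums to repeats × per-class test count, and per-class accuracy
is the diagonal over the row sum. Raw descriptor fields are extracted once
per image and reused across repeats — this is a pure computation cache;
PCA/GMM/classifier fits see training rows only (the suite tests that
replacing test images does not move the fitted GMM).

**Scalability.** For each subset size n (default `{3, 6, ..., 31}`) and each
of 25 repeats, n classes are drawn at random and one equal-split evaluation
with the reference classifier is run on that subset. Accuracy in percent is
regressed on n by OLS once per repeat; the extrapolated accuracy at a target
class count (default 100) is the mean of the per-repeat predictions and the
quoted uncertainty is their standard deviation. A pooled fit supplies the
reported slope/intercept. The uncertainty definition is a documented choice:
"±" could equally be the pooled prediction's standard error, and the
per-repeat definition is the one this package reports.

## The synthetic generator

`generate_image()` emulates what distinguishes the morphotypes in real
Gram-stained smears: particle shape (disc / rod / curved rod), size,
density, and arrangement (solitary, chains advancing along a jittered
direction, isotropic clusters), rendered dark-on-bright with anti-aliased
edges, additive Gaussian noise, and 8-bit quantization so in-memory images
equal their PNG round trip. It deliberately does **not** simulate color
(Gram hue), uneven illumination, focus blur, or biophysical colony growth —
so a passing synthetic benchmark demonstrates that the pipeline separates
texture classes defined by shape/arrangement statistics, not that any
particular accuracy carries over to real micrographs.

Two presets are frozen as study conditions: `demo5` (five classes spanning
the shape × arrangement axes, 96 × 96 px) and `scale12` (twelve classes
crossing shape, arrangement, size and density, 64 × 64 px, for the
scalability machinery). Their parameters were written once from the
morphotype descriptions and are versioned in code.

## Problem sizes used by the tests and the acceptance script

These are the package's own desk-scale choices: the `demo5` benchmark runs
20 images/class at 96 × 96 px, 10/10 splits, 5 repeats, with `gmm_k = 32`,
`pca_dim = 32`, `subsample = 20000` (half the default component count keeps
the EM fit, the dominant cost, proportionate to the roughly 50k training
descriptors such a run pools). The scalability study runs `scale12` at
64 × 64 px with n ∈ {3, 6, 9}, 3 repeats, `gmm_k = 16`, `pca_dim = 24` —
it exercises the subset/regression machinery, whose checks (exact-line
recovery, completion, monotone trend) do not depend on absolute accuracy.
Oracle comparisons use N ≤ 200 descriptors, K ≤ 4, d ≤ 16, where the naive
double-loop encoder is exact and fast.

## Design decisions that were genuinely open

- **SIFT layout.** 4 × 4 × 8 is the only layout consistent with dimension
  128; bin size, scale count and boundary handling are configuration with
  the defaults above (single scale, no padding).
- **FV normalization** (`ssr_l2`) and the **exclusion of zeroth-order
  statistics** follow the first/second-order definition of the encoder.
- **PCA before the GMM** is on for SIFT (128 → 64 by default) and off for
  deep descriptors.
- **"Random Forest (with AdaBoost algorithm)"** is contradictory as a
  label — a bagged forest and AdaBoost are different ensembles. The
  parenthetical names the algorithm, so the package implements boosted
  trees (SAMME) under the tag `rf-adaboost`.
- **Bayesian optimization internals** (GP surrogate with squared-exponential
  kernel, lengthscale by marginal likelihood on a fixed grid, expected
  improvement over seeded Latin-hypercube candidates, 5-fold stratified CV
  objective) are documented defaults; the default configuration (C = 1) is
  always evaluated first, so the tuned model never scores below it in CV.
- **Grayscale conversion** uses ITU-R 601 luminance weights. The descriptors
  are gradient/intensity based; exploiting the Gram-stain color distribution
  is a known extension, deliberately out of scope.
- **Pretrained backends.** AlexNet/VGG-class extractors are an adapter
  contract (`feature_backend()` + `register_backend()`); nothing in the
  package bundles or requires weights, and an unregistered backend fails
  loudly rather than silently falling back. The seeded toy filter bank
  (8 random 3 × 3 filters, stride 4, rectification, replicate-edge padding)
  exists to exercise the FV-CNN/FC-CNN code paths.

## Known limitations

- Dense SIFT is single-scale by default; strongly size-varying textures may
  benefit from `extract_dsift_multiscale()`.
- The Fisher encoder assumes diagonal covariances; heavily correlated
  descriptor dimensions should be PCA-projected first.
- The synthetic benchmark bounds what the tests can show about real
  micrographs (see above); absolute accuracies on DIBaS-style data require
  the real images and, for the deep variants, real pretrained weights.
- One-vs-all linear SVMs need classes to be linearly separable from the
  rest in representation space; this holds for high-dimensional Fisher
  Vectors but can fail in low-dimensional toy feature spaces.

## Worked example

```{r example}
library(bactex)

idx <- generate_dataset(get_preset("demo5"), images_per_class = 20,
                        size = c(96, 96), seed = 2024)
report <- run_repeated_eval(idx,
                            encoder_config(gmm_k = 32, pca_dim = 32,
                                           subsample = 20000),
                            classifier_config("original"),
                            recipe = "FV-SIFT", repeats = 5,
                            per_class_train = 10, seed = 2024)
print(report)
report$per_class_accuracy
```

The same run from a shell, via the bundled CLI:

```sh
Rscript inst/cli/bactex evaluate --preset demo5 --recipe FV-SIFT \
  --classifier original --gmm-k 32 --pca-dim 32 --subsample 20000 \
  --repeats 5 --seed 2024 --out runs/demo5
```
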