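---
title: "Weakly supervised hand-radiograph segmentation with a dual-attention U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised hand-radiograph segmentation with a dual-attention U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raxseg)
```

## The problem

Plain radiography is the workhorse modality for structural damage assessment
in rheumatoid arthritis, but joint-level quantification needs pixel-accurate
segmentation of hand structures — thin cortical rims, overlapping phalanges
and carpals, low-contrast joint spaces — and expert pixel annotation is
scarce. `raxseg` implements a complete, CPU-testable pipeline for this
setting: classical weak supervision (CLAHE + Otsu pseudo-masks) to
manufacture training labels, an attention-gated encoder–decoder network, a
composite overlap-centric objective, and a boundary-aware evaluation and
ablation harness. Everything runs offline; a seeded synthetic phantom
generator stands in for real radiographs so that every stage is testable
without data downloads.

## The phantom generator: what it emulates and what it does not

`generate_phantom()` draws a hand silhouette — a palm ellipse, a carpal
block, and finger capsules (rectangles with semicircular caps) crossed by
2–4 px joint gaps — and renders it as soft-tissue halo plus brighter bone
foreground, multiplied by a smooth positive bias field and degraded with
Gaussian noise. The generator is calibrated to the population statistics of
the public hand-radiograph collection the pipeline targets:

* mean foreground coverage near 35% per image, with a mild left tail
  (`coverage_target = 0.35`; per-sample targets are jittered with a skewed
  perturbation and the silhouette scale is solved per sample);
* bimodal per-image mean intensity with modes near 0.30 (under-exposed) and
  0.60 (bright), implemented as two exposure regimes
  (`intensity_modes = c(0.30, 0.60)`);
* low-frequency multiplicative shading: an exponentiated sum of 2–3
  low-order 2-D cosine terms with random phase, relative amplitude
  `bias_strength = 0.15`;
* additive noise `noise_sigma = 0.02` on the [0, 1] scale. The source
  collection does not report a noise model or per-image variance, so this
  default is our choice of a plausible radiographic noise floor, not a
  calibrated value.

Capsule foregrounds give thin, low-contrast boundaries comparable to
cortical rims, which is what the boundary metrics are meant to stress. The
phantoms are deliberately *not* photo-realistic: no trabecular texture, no
erosion lesions, no DICOM semantics, and foreground/background intensities
are by construction bimodal. Consequently, passing tests demonstrate that
the machinery is correct and that learning converges on well-separated
foregrounds; they do not demonstrate real-radiograph accuracy, which
additionally depends on pretrained encoders and expert-validated data.

All per-sample randomness flows from one seed; the generator never touches
the caller's RNG stream.

## Preprocessing

* **Percentile windowing** (defaults 1st/99th percentile) clips and rescales
  to [0, 1]. Quantiles use the inverse-ECDF definition (type 1), which makes
  the operation exactly idempotent — re-windowing a windowed image is a
  no-op to machine precision.
* **Bias-field removal**. The inputs are 2-D radiographs, so we define the
  *contract* — estimate a smooth, strictly positive multiplicative field
  with mean one and divide it out — and implement a robust homomorphic
  estimator: bright anatomy is excluded via an Otsu threshold with a dilated
  margin, and the log image is fitted on the remaining background and
  soft-tissue pixels with a low-order 2-D Fourier surface by iteratively
  reweighted least squares (Huber weights). A parametric low-frequency fit
  is used instead of plain log-domain smoothing because a smoothing kernel
  attenuates each spatial frequency differently and therefore distorts the
  shape of the recovered field; the parametric fit recovers the generator's
  cosine fields with correlation above 0.9 and strictly reduces the
  coefficient of variation of background pixels.
* **Standardization**: per-image z-score by default (sd floored at 1e-8);
  min–max scaling available. Histogram-based standardization across studies
  is intentionally not implemented. An optional monotone gamma mapping in
  [0.8, 1.2] is off by default.
* **Geometry**: bilinear resampling for images, nearest-neighbor for masks
  (labels stay strictly binary), half-pixel-center convention, row-major
  (row, col) coordinates with the origin at the top-left.
* **Augmentation** (`augment_policy()`): rotations up to ±10°, scales
  0.9–1.1, translations up to 5% of the side, flips with probability 0.5,
  mild elastic deformation (4×4 control grid, 2 px displacement sigma),
  intensity jitter ±10% and additive noise. Every spatial transform is
  mirrored on the mask with nearest-neighbor sampling; intensity operations
  never touch the mask. A policy with degenerate ranges is an exact
  identity, which the tests exploit.

## Pseudo-mask weak supervision

`make_pseudo_mask()` enhances local contrast with CLAHE (clip limit 2.0,
8×8 tiles), computes a single *global* Otsu threshold on the enhanced image,
relaxes it by the factor 0.95, applies light morphological opening then
closing (disk radii 2 px at 256×256), and keeps the largest 8-connected
component. Choices worth noting:

* Otsu is computed globally after CLAHE, not per tile; both the tile grid
  and the structuring-element radii are configurable because the recipe's
  source leaves them open.
* The threshold search maximizes between-class variance over a 256-bin
  histogram; when a histogram gap produces a plateau of equivalent maxima,
  the plateau midpoint is returned so the cut sits between the modes.
* Ties in largest-component size are broken deterministically by the first
  pixel in column-major order.
* Empty masks are data, not errors: a constant image yields an empty mask
  with a warning, and all downstream metrics have explicit empty-mask
  conventions.

On noise-free phantoms the pipeline recovers the true silhouette with Dice
above 0.97; `evaluate_pseudo()` quantifies agreement with reference masks by
Dice, IoU, boundary F1, boundary pixel accuracy, ASSD and HD95.

## The network

The model is an encoder–decoder with a pluggable four-stage feature-pyramid
encoder tapped at strides 4/8/16/32 (E1..E4) and exactly three up-sampling
blocks consuming skips E3, E2, E1. Each up block is: bilinear ×2 upsample →
skip concatenation → two (Conv 3×3 → BatchNorm → SiLU) layers. Attention is
placed as follows:

* **Up block 1**: the E3 skip is recalibrated by an scSE gate *before*
  concatenation (modes `scse` and `cbam_scse` only — the `cbam` mode
  contains no squeeze-excitation anywhere, so ablations isolate each gate).
* **Up blocks 2–3**: CBAM on the concatenated tensor (channel gate =
  sigmoid of a shared two-layer MLP over average- and max-pooled
  descriptors, reduction 16; spatial gate = sigmoid of a 7×7 convolution
  over the channel-mean and channel-max maps), then scSE after the
  convolution pair. scSE is the additive combination
  `x·sigmoid(MLP(gap(x))) + x·sigmoid(conv1x1(x))`.
* Decoder dropout (default 0.1) is applied at the end of each block, after
  the attention gate.
* The decoder ends at stride 4; a parameter-free bilinear ×4 upsample
  precedes the 1×1 convolution head and sigmoid. Optional deep supervision
  attaches auxiliary sigmoid heads after up blocks 1 and 2 with loss
  weights 0.4 and 0.2.

Decoder widths default to (256, 128, 64); `slim_model_config()` pairs the
tiny `slim-test` encoder (< 100k parameters) with widths (32, 24, 16) for
CPU-scale work. Since no deep-learning runtime exists for R, the layers —
im2col convolutions, batch normalization, SiLU, bilinear resampling, the
attention gates, and AdamW with decoupled weight decay — are implemented in
the package and validated by finite-difference gradient checks.

The named large backbones (EfficientNet-B0/B3, ResNet50, ConvNeXt-Tiny) are
realized as randomly initialized pyramid encoders with the reference stage
widths and strides: the package ships no pretrained weights, so these
provide architecture-shaped capacity for the ablation harness rather than
transfer learning. `profile_backbone()` is exact about the reference
architectures: it reproduces, layer by layer, the trainable-parameter count
and forward multiply-accumulate count of the standard ImageNet
classification networks (1000-class heads included, 224×224 inputs except
300×300 for B3), and reports FP32 size as 4 bytes per parameter. FLOPs
figures follow the MAC-counting convention.

## The objective

Training minimizes

$$L = 0.45\,L_{\mathrm{Dice}} + 0.35\,L_{\mathrm{BCE}} + 0.20\,L_{\mathrm{Lovász}}.$$

* $L_{\mathrm{Dice}}$ is the soft Dice loss with the squared-denominator
  form $1 - (2\sum p_i y_i + \varepsilon)/(\sum p_i^2 + \sum y_i^2 +
  \varepsilon)$, evaluated on sigmoid-transformed logits ("Dice over
  logits" is read as sigmoid-inside-the-loss; a Dice on unbounded raw
  logits is ill-defined). The *metric* Dice used for evaluation is the set
  form on binarized masks; both exist and are named apart.
* $L_{\mathrm{BCE}}$ is binary cross-entropy computed in the logit domain
  (stable for $|z|$ up to 1e4).
* $L_{\mathrm{Lovász}}$ is the Lovász hinge: hinge errors
  $e_i = 1 - z_i(2y_i - 1)$ sorted descending, dotted with the discrete
  Jaccard gradient of the Lovász extension. It is computed per image and
  averaged — batch-flattened computation would change the optimum. The
  implementation is verified against an exhaustive prefix-Jaccard oracle
  over all $2^6$ label patterns.
* $\varepsilon = 10^{-6}$ enters numerator and denominator of Dice and
  Tversky so that empty-prediction/empty-label cases score zero loss.
* Tversky ($\alpha$, $\beta$ on soft FP/FN counts) and Focal-Dice are
  provided for evaluation studies but are not part of the default
  objective. The printed Focal-Dice form is ambiguous between
  $1-\mathrm{Dice}^\gamma$ and $(1-\mathrm{Dice})^\gamma$; the first is the
  default, the second sits behind a `variant` flag.

## Evaluation

Per-image metrics: set-form Dice and IoU (with
$\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ as an invariant), pixel
accuracy, precision/recall/F1, background leakage rate, boundary F1 and
boundary pixel accuracy, ASSD, HD95, surface Dice, and pooled ROC/PR AUCs.
Conventions, chosen once and tested:

* **Leakage rate** has no printed formula in the source literature; it is
  defined here as $FP/(TP+FP) = 1 - \text{precision}$ (0 when nothing is
  predicted), which tracks observed ablation behaviour at realistic
  Dice levels.
* **Boundaries** are mask minus its 3×3-cross erosion, with outside-image
  treated as background. The boundary tolerance defaults to 2 px at 256×256
  and should scale linearly with the side. Boundary pixel accuracy is pixel
  accuracy restricted to the band within the tolerance of the reference
  boundary.
* **Surface distances** are Euclidean between boundary-pixel centers,
  computed with a distance transform and verified against an all-pairs
  oracle. HD95 is the 95th percentile of the *pooled* directed distances
  (pooling, rather than max-of-directions, is the package's choice where
  the source is silent). Both-empty pairs score 0 (surface Dice 1);
  one-empty pairs yield missing values that are excluded from summaries and
  counted.
* **ROC-AUC** is the tie-aware rank statistic (normalized Mann–Whitney U);
  PR-AUC integrates the interpolated precision envelope. Pooling is over
  whatever pixels the caller supplies; whole-split pooling matches a single
  printed AUC per split.
* **Bootstrap summaries** report mean ± SD and a seeded non-parametric
  percentile CI of the resampled mean (B = 2000, level 0.95). The CI is on
  the mean, not on the value distribution.
* **Paired Wilcoxon** delegates to the standard signed-rank implementation:
  zero differences dropped, exact null for n ≤ 25, normal approximation
  with continuity correction above.

## Training protocol

Patient-level splits stratify patients by mean foreground-coverage quartile
(the task is binary, so coverage quartiles replace class stratification) and
assign each patient wholly to one split. Image-count targets are
floor(0.70 N) / round-half-up(0.15 N) / remainder — at N = 185 this gives
129/28/28; a pure floor rule would give 129/27/29, and the adopted rounding
matches the reference protocol's stated counts.

Optimization is AdamW (decoupled weight decay 1e-4, applied to matrix-shaped
parameters only), a 2-epoch linear warm-up to the base rate followed by
cosine decay to zero, applied per optimization step (per-epoch mode
available); the schedule is continuous at the junction, exactly the base
rate at warm-up end, half of it at the cosine midpoint and zero at the final
step. Checkpoints are selected by best validation Dice at threshold 0.5,
ties within 1e-6 broken by lower validation loss, then by earlier epoch.
Early stopping is off by default (fixed 15-epoch schedule); a patience knob
exists. Inference offers a fixed 0.5 threshold (default), a validation
threshold sweep over 0.05–0.95 (ties resolved to the middle of the
maximizing set), and flip test-time augmentation (mean of four aligned
passes, which symmetrizes predictions under flips by construction).

### Desk-scale problem sizes

The test suite and the acceptance script run everything at sizes chosen for
a single CPU: 64×64 phantoms, the `slim-test` encoder with decoder widths
(32, 24, 16), batches of 8, and 200 optimization steps for the convergence
smoke test (32 training phantoms, 3 seeds, held-out Dice ≥ 0.80). The
smoke configuration uses a peak learning rate of 1e-3: the full-scale
default of 1e-4 is appropriate for fine-tuning a pretrained encoder over a
long schedule, while a tiny randomly initialized network trained for a few
hundred steps needs the conventional from-scratch rate. The end-to-end demo
(60 phantoms → pseudo-masks → patient splits → 10 training epochs under
weak supervision → dual-policy evaluation with TTA → JSON report) completes
in well under a minute. The full-scale recipe — 256×256 inputs, batch 16,
15 epochs, learning rate 1e-4 — remains the package default in
`train_config()`.

## Known limitations

* Headline real-data accuracy requires the external radiograph collection,
  pretrained encoders and GPU-scale training; this package reproduces the
  protocols and verifies the machinery, not those numbers.
* The named large encoders are architecture-shaped but untrained; transfer
  behavior is out of scope.
* Binary segmentation only (the head accepts C channels but only C = 1 is
  exercised); 2-D only; no calibration metrics.
* Pseudo-masks inherit the classical pipeline's biases: they are
  intensity-driven and will under-segment structures that do not separate
  from soft tissue by a global threshold.
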