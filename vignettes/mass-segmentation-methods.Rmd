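---
title: "Methods: connected U-Nets for breast mass segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connected U-Nets for breast mass segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Screening mammography pipelines for mass lesions typically run in two
stages: a detector localizes suspicious regions of interest (ROIs), and a
segmentation network delineates the mass within each detected crop.
`mammoseg` implements the segmentation stage as a family of encoder–decoder
networks operating on 256×256 grayscale ROIs (any power-of-two-compatible
side works), plus everything around it: data preparation, the training
loss, evaluation metrics, mask cleanup, and end-to-end accuracy
bookkeeping. The detection stage is represented only by its accuracy rate,
a scalar that enters the final accuracy measure.

Six architecture variants are available through `model_spec()`:

* **Standard U-Net** — encoder blocks (two 3×3 convolution units each,
  followed by 2×2 max pooling), an atrous spatial pyramid pooling (ASPP)
  transition, and decoder blocks (2×2 transposed convolution, skip
  concatenation, two convolution units), closed by a 1×1 convolution and a
  sigmoid. A convolution unit is conv → ReLU → batch norm; this unusual
  ordering is deliberate and is the package default, with `bn_first = TRUE`
  switching to the conventional conv → BN → ReLU.
* **Attention U-Net (AUNet)** — the same network with additive attention
  gates on the decoder skips: 1×1 projections of skip and gate are summed,
  passed through ReLU, projected to one channel, and squashed to a
  coefficient map α ∈ (0,1) that weights the skip.
* **Residual U-Net (ResUNet)** — convolution blocks replaced by residual
  blocks (two convolution units plus an identity or 1×1-projected shortcut,
  summed before a final ReLU).
* **Connected** variants of all three — two cascaded U-Nets. The first
  decoder's full-resolution output, concatenated with a 3×3-convolved copy
  of itself, bridges into the second encoder. Each deeper second-encoder
  level receives its pooled input after a 3×3 convolution unit,
  concatenated with the first decoder's output at the same resolution —
  skip connections running decoder→encoder, mirroring the classic
  encoder→decoder skips. A second ASPP and decoder follow, then the head.

The ASPP transition applies parallel 3×3 convolutions at dilation rates
(1, 6, 12, 18) by default, each conv → ReLU → BN, concatenates the branches
and fuses them with a 1×1 convolution. At the default depth (4 poolings of
a 256 input) the bottleneck is 16×16, smaller than the largest dilation
offset; with zero padding such a branch degenerates smoothly toward its
center tap, so any strictly increasing rate set is accepted rather than
rejected.

Channel widths follow the standard doubling schedule (32, 64, 128, 256 from
`base_filters = 32`, with 512 ASPP channels); none of these widths are
fixed by the architecture definition, so they are all `model_spec()`
parameters. Weight initialization is He-uniform, seeded via
`build_model(spec, seed)`.

The network forward/backward passes are implemented natively: convolutions
lower to BLAS matrix products through im2col (compiled kernels in
`src/kernels.cpp`, with plain-R reference implementations kept as test
oracles), and a small reverse-mode tape differentiates the full graph. The
test suite verifies every kernel's gradient against central finite
differences and checks that every trainable tensor of all six variants
receives a gradient — the property that catches mis-wired skip connections.

## Loss, metrics, and accuracy bookkeeping

Training minimizes a weighted sum of soft Dice and IoU losses,
`-(0.4·Dice + 0.6·IoU)` (`loss_weights()`), with a smoothing constant of 1
in numerator and denominator. Two deliberate choices:

* **Batch pooling.** The training loss flattens the whole mini-batch into
  one pixel set before forming the overlap ratios, the convention of the
  common Keras Dice/Jaccard loss implementations. The per-sample
  alternative (score each ROI, then average) makes the per-pixel gradient
  scale like 1/|mask|; ROIs with very small masses then overshoot into
  saturated all-foreground predictions within a few Adam steps and stay
  frozen there (the sigmoid gradient underflows while Adam's second-moment
  memory keeps step sizes tiny). We observed exactly this failure on small
  phantoms; under the pooled loss all samples converge.
* **Exact evaluation.** Reported metrics use `smooth = 0` on binarized
  predictions (threshold 0.5, the sigmoid midpoint), so evaluated Dice and
  IoU are the exact set-overlap quantities, with the both-empty pair scored
  as 1. Per-ROI percentages are rounded half-up to two decimals.

`iou_90()` averages per-ROI IoU percentages over ROIs at or above 90%
(inclusive threshold) and is "not applicable" (`NA`) when none qualify.
`final_segmentation_accuracy()` multiplies an externally supplied detection
accuracy rate by IoU\_90/100, composing the two pipeline stages into one
end-to-end figure; `final_accuracy_inputs()` ships the nine published
operating points used as worked examples. Pixel-wise ROC/AUC pools all
pixels of a test set, min-max normalizes the soft scores, and integrates
TPR over FPR by the trapezoid rule; ties are collapsed to single ROC
vertices so the AUC equals the Mann–Whitney statistic.

## Data preparation

`resize_roi()` implements the two-kernel policy for detected crops:
Catmull-Rom bicubic interpolation when the image is smaller than the
256-pixel target, pixel-area averaging ("inter-area") otherwise, with the
output re-clipped to the input range; masks are resampled nearest-neighbor
so they stay binary. No installed package offers these kernels for plain
matrices, so they are built as separable resampling matrices.

`equalize_and_normalize()` performs global histogram equalization followed
by min-max scaling to [0, 1]. It is implemented rank-based (empirical CDF)
rather than through a 256-bin histogram: the two properties one wants from
equalization — idempotence and invariance to monotone intensity remaps —
then hold exactly instead of approximately, which also makes them crisp
tests.

`augment_six()` expands each ROI six-fold: rotations by 0°, 90°, 180°, 270°
(the 0° member *is* the original, which is the only reading under which
1467 raw ROIs yield exactly 8802) with co-rotated masks, plus two CLAHE
variants that touch only intensities. The CLAHE parameter pairs are not
pinned by the recipe's definition; the defaults are a mild (clip limit 2,
8×8 tile grid) and a strong (clip limit 4, 16×16 grid) enhancement, two
clearly distinct strengths. `tile_grid` counts tiles per side, the
convention the default values come from.

`split_dataset()` assigns 70/20/10 train/test/validation fractions. In
`"paper"` mode the augmented samples are shuffled directly; the allocation
rule is floor(0.7·N) for train, round-half-up(0.2·N) for test, remainder to
validation — the only rounding consistent with all three published
per-dataset rows (8802 → 6161/1760/881, 672 → 470/134/68,
3828 → 2679/766/383; note 0.2·3828 = 765.6 prints as 766, which floor would
miss). Splitting augmented copies independently leaks near-duplicates
across partitions, so the default mode is `"grouped"`: whole parent-ROI
groups are allocated together, and `"paper"` mode exists to reproduce the
published counts.

## The phantom generator

`phantom_spec()`/`generate_phantom()` produce mammogram-like ROI phantoms
so the whole pipeline is testable without clinical data. Each phantom is:

* a **lesion**: an ellipse whose radius is modulated by a random low-order
  Fourier series (harmonics 2–5, amplitude `boundary_irregularity`,
  clamped so the region stays star-shaped and hence connected), rendered
  with a Gaussian-blurred edge and added to the background with mean
  intensity gap `mass_contrast`. Star-shaped regions have computable areas:
  at zero irregularity the mask area equals π·a·b to within discretization,
  one of the generator's tests. The edge blur scales with lesion size
  (σ = max(0.8, 0.08·√(ab)) px) so the rendered appearance is invariant to
  the image side — a fixed-width blur would swamp small phantoms entirely.
* a **background**: Gaussian-filtered white noise (correlation length
  `background_texture_scale`) plus a random linear illumination ramp —
  low-contrast structure that histogram equalization visibly improves —
  plus i.i.d. pixel noise.

The mask is the exact pre-blur region, one connected component per phantom
(the networks segment single detected ROIs). Generation is a pure function
of `(spec, index)`: each sample derives a private RNG stream, so datasets
are bit-reproducible and any sample can be regenerated independently.
`generate_dataset()` writes 8-bit PNGs with a relative-path CSV manifest,
making runs into different directories byte-identical.

`shift_domain()` stands in for cross-dataset style synthesis with a
deterministic transform (gamma curve, contrast rescale about the mean,
seeded noise) that preserves the mask exactly — the property that matters
for using style-transferred copies as extra annotated data. It makes no
attempt to learn a mapping between domains; adversarial synthesis is out of
scope.

What phantoms do **not** emulate: spiculated margins and architectural
distortion, calcifications, pectoral muscle and skin-line structure,
scanner-specific noise, or multi-lesion scenes. Passing the learning tests
therefore shows that the architectures, loss, and training loop optimize
and generalize on bright irregular blobs over textured backgrounds — a
necessary sanity property — not that clinical-grade accuracy is reproduced;
the published Dice/IoU tables on CBIS-DDSM/INbreast require those datasets
and are deliberately not targets.

## Training

`training_config()` carries the production constants: Adam (β₁ = 0.9,
β₂ = 0.999, ε = 1e-7), learning rate 1e-4, 100 epochs, batch size 8 — "8
mini-batches" read as a batch size of 8, the standard usage. Augmentation
is applied offline once (the published counts imply offline), the training
set is reshuffled each epoch under the config seed, and runs are
bit-reproducible given the init and config seeds. Per-epoch training and
validation loss/Dice are logged; the best-validation and final weights are
checkpointed. The validation set is monitor-only: no early stopping and no
learning-rate schedule. Non-finite losses abort with a diagnostic rather
than training through NaNs. `train()` accepts a missing validation set
(metrics `NA`) so that small sanity fixtures can train on all samples,
while the manifest-driven `cmd_train()` insists on both partitions.

## Post-processing

`largest_component_mask()` implements the cleanup applied to predicted
masks before scoring: extract all contours, keep only the one enclosing
the largest area. Components are 8-connected (diagonally touching
fragments are one object), holes inside the winning outer contour are
filled — selecting by *enclosed* area implies filling — and area ties break
by higher mean soft score, then lowest raster index, keeping the operation
deterministic. Empty predictions pass through flagged rather than
fabricating a region, and score IoU 0 against non-empty truth.
`extract_contour()` returns the ordered outer boundary for overlays and
shoelace-area checks.

## Desk-scale problem sizes

The learning tests and the acceptance script run on phantom sets sized for
a desk machine; all sizes below are the package's own choices, stated here
so the measurements are interpretable:

* **Overfit sanity**: the connected U-Net (`base_filters = 16`) trains on
  8 phantoms at 32×32 for 200 full-batch steps at learning rate 3e-3 and is
  expected to exceed 0.95 training Dice. The production learning rate of
  1e-4 is appropriate for 100-epoch runs on thousands of ROIs but far too
  slow for a 200-step overfit (it reaches ≈0.8); the fixture therefore uses
  the larger rate.
* **Generalization comparison**: 60 phantoms at 32×32 are prepared with
  the full six-fold recipe and a grouped split (252/72/36 samples); the
  standard and connected U-Nets (base 16) each train ~100 steps at 1e-3 and
  are compared by held-out test Dice (three seeds in the test suite). The
  expectation is relative — connecting the two U-Nets should not *hurt* —
  because at this scale and training budget either variant can win a given
  seed.
* 32×32 keeps a connected-model training step around a second on one core;
  the same code runs unchanged at 256×256.

## Numerical choices and limitations

* Sigmoid outputs are clamped to [1e-12, 1 − 1e-12] so probability maps are
  strictly interior even when pre-activations saturate in double precision.
* Max-pool gradients route to the first maximal element of each window in
  raster order; batch-norm uses biased batch variance, momentum 0.9 running
  statistics, and ε = 1e-5.
* Batch norm after ReLU (the default unit order) normalizes a rectified,
  hence non-negative, activation; this is followed as specified, and
  `bn_first` exists for the conventional order. Both orders train on the
  fixtures.
* The implementation is CPU-only and single-threaded by design of the
  environment; convolution GEMMs dominate the profile. Training at
  clinical scale (256×256, thousands of ROIs, 100 epochs) is functional
  but slow — hours, not minutes — and is not exercised by the tests.
* Whether published aggregate scores are means of per-ROI scores or
  pooled-pixel scores is not stated in their source; per-ROI means are
  used here and the pixel-pooled view appears only in the ROC/AUC
  methodology.
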