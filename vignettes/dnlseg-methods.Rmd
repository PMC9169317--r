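---
title: "Segmenting blood vessels with deformed non-local attention: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting blood vessels with deformed non-local attention: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnlseg)
```

## The problem

Vascular disease diagnosis leans on accurate pixel-level segmentation of
blood vessels in 2D medical images: intracranial CT-angiography slices and
retinal fundus photographs are the canonical settings.  Vessels are thin,
curvilinear, low-contrast structures spanning the whole image, which makes
two properties of a segmentation network matter simultaneously: long-range
context (a vessel is a connected tree, not a local texture) and multi-scale
sensitivity (calibres range from one pixel to dozens).

Standard non-local (NL) self-attention supplies long-range context by
comparing every spatial position with every other one.  For a `C x H x W`
feature map the attention-times-value product costs on the order of
`C * (HW)^2` multiply-accumulates, which is prohibitive at segmentation
resolutions (`HW = 262,144` at 512 x 512).  The network implemented here
replaces the positional attention with a *channel-similarity* attention of
size `C x C` — the deformed non-local (DNL) block — reducing that product to
`HW * C^2`, i.e. by a factor of exactly `HW / C` (certified analytically by
`fg_product_op_counts()`).

## The architecture

`dnl_net()` assembles a U-shaped encoder–decoder:

* **Encoder** — `n_stages` stages of two `3x3 conv -> batch norm -> ReLU`
  layers, 2x2 max-pooling between stages, channel width doubling per stage.
  A plain Conv+BN encoder is used deliberately: regions of interest in
  medical images are sparse, and heavier pretrained backbones lose thin
  structures.
* **Bottleneck** — two widening Conv+BN+ReLU layers followed by **RSEP**
  (residual squeeze-and-excitation pyramid pooling): four parallel 3x3
  atrous-convolution branches with dilations 1/6/12/12, each followed by an
  SE gate, a 1x1 convolution and a ReLU; the input map is concatenated with
  the four branch outputs and fused by a 1x1 convolution back to the input
  width, so the module is drop-in.
* **Decoder** — per stage, **MFF** (multi-scale feature fusion): the deep
  feature is refined by a DNL block; its channel-attention vector
  `AV = sigma(Conv1x1(L2Normalize(GAP(.))))` gates the encoder skip feature;
  the deep feature itself is projected by a 1x1 convolution, upsampled x2
  (bilinear by default) and added.  Two Conv+BN+ReLU layers follow.
* **Head** — a 1x1 convolution and a sigmoid, giving per-pixel vessel
  probabilities.

### The DNL block in detail

With the map flattened to `C x HW` and 1x1-convolution embeddings
`theta, phi, g : C -> Cbar`:

1. channel attention `A = softmax(theta(x) phi(x)^T)`, a `Cbar x Cbar`
   row-stochastic matrix (each query channel's distribution over key
   channels);
2. `y1 = A g(x)` (`Cbar x HW`);
3. a 1-channel projection of `x` is pooled against `y1`, giving a
   length-`Cbar` descriptor `y2 = pool(x) y1^T`;
4. a reduce/expand bottleneck (`Cbar -> Cbar/rate -> C`) turns `y2` into
   channel weights `y4`;
5. `y4` is broadcast-multiplied into a 1x1-convolved copy of `x`, an SE tail
   re-adjusts the channels, and the input is added residually.

Interpretation choices where the formulation is ambiguous (all configurable,
defaults stated):

* The unnormalised similarity is exponentiated once *inside* the softmax,
  not separately before it — the exponential form is the softmax's
  numerator, and a double exponentiation would be numerically explosive.
* Softmax normalisation runs row-wise over the second channel index,
  mirroring the per-query normalisation of positional attention.
* The descriptor is oriented `1 x Cbar` so steps 3–5 chain dimensionally.
* No activation is specified between the bottleneck maps; we insert a ReLU
  after the reduce map and a sigmoid on `y4`, mirroring the SE convention
  the bottleneck imitates (`bottleneck_activation = "none"`,
  `gate = "none"` switch them off).
* The final 1x1 convolution acts on `x` and its output is gated
  channel-wise by `y4` (broadcast element-wise product).
* `Cbar` defaults to `C` (no embedding bottleneck); `rate` defaults to 4 and
  the SE reductions to 16, clamped per stage to the largest divisor of the
  stage width so narrow test presets stay valid.

### MFF and RSEP choices

* The deeper/coarser decoder feature drives the attention vector and the
  upsampled term; the encoder skip feature is the gated one.  (The
  formulation's prose swaps the two labels; the figure-consistent binding is
  used.)
* The x2 upsampling operator is unstated; bilinear with half-pixel centres
  is the default, nearest-neighbour available.  A 1x1 projection aligns
  deep channels to skip channels before the addition, since channel
  matching is unspecified.
* RSEP branches run in parallel (the "cascade" wording could also be read
  sequentially; the module figure shows parallel branches).  The duplicated
  dilation 12 is implemented as printed; `rsep_config(dilations =
  c(1, 6, 12, 18))` gives the conventional ASPP ladder if the duplication is
  suspected to be a typo.  The input-map concatenation happens after the
  branch ReLUs.  Dilations padding beyond the current map raise a warning,
  not an error — the arithmetic is still exact.

## Training

`dnlnet_train()` optimises `dice_w * DiceLoss + wce_w * WeightedCE` with
ADAM (`beta1 = 0.5`, `beta2 = 0.999`), initial learning rate `1e-3` decayed
per epoch by `(1 - (epoch - 1)/total)^0.9`, 200 epochs and batch size 4 in
the full recipe (`train_config(preset = "paper")`); the soft Dice loss is
`1 - 2 sum(pq) / (sum(p^2) + sum(q^2))` and the cross-entropy weights the
vessel class by the per-batch background/vessel pixel ratio by default
(`w_pos = "auto"`), the standard imbalance handling; both loss weights
default to 1 since the combination is unweighted in its source.  The decay
schedule is applied per epoch (the formula is written in epochs).  20% of
the corpus is held out as a seeded validation split and the
best-validation-Dice parameters are retained.

Numerical conventions: losses and Dice denominators are stabilised with
`eps = 1e-7`; predictions are clamped to `[eps, 1 - eps]` inside the
cross-entropy; softmax subtracts the row maximum; max-pool ties resolve to
the first element in fixed slab order; batch norm uses batch statistics in
training and running averages (momentum 0.1) in evaluation.

Preprocessing for fundus-style imagery (`preprocess_drive_style()`) applies
gray-scale conversion, per-image standardisation, CLAHE and gamma
adjustment in that order; CLAHE and gamma act on min-max-rescaled
intensities so the output lands in `[0, 1]`.  Training patches (96 x 96 in
the full recipe) are sampled with uniformly random centres; windows
crossing the border are reflect-padded rather than rejected so border
vessels stay represented.  CTA-style augmentation composes a small random
affine distortion, rotation and vertical flip, identically on image and
mask, with nearest-neighbour resampling keeping masks binary.

## Gradients: a native autodiff engine

The package deliberately carries no deep-learning-framework dependency: it
ships a small tape-based reverse-mode automatic-differentiation engine
(`R/autodiff.R`) over dense `N x C x H x W` arrays, with compiled kernels
(im2col + GEMM convolution with cached column matrices, batched matrix
products, pooling, channel broadcasts) behind the hot paths.  Every block
runs through the same ops whether called as a pure function or inside
training, so the oracle-tested arithmetic is exactly the trained
arithmetic.  The test suite verifies the engine end to end by comparing
autodiff gradients of the full combined loss against central finite
differences on a 1% sample of parameters (relative tolerance `1e-3`).

## The phantom generator

Real CTA and fundus datasets are either private or external downloads, so
every claim in this package is exercised on `generate_phantom()` output:
seeded curvilinear strokes (splines through jittered waypoints, dilated to
a sampled width) whose union is the *exact* binary mask, painted over a
uniform background, Gaussian-blurred and corrupted with Gaussian pixel
noise.  Strokes are added while the mask stays within a 25% foreground
budget, so the foreground fraction is bounded by construction.

The default CTA preset uses vessel intensity 0.65 over background 0.35 with
blur 0.8 and noise 0.18 — a thin-vessel contrast-to-noise ratio near 1.3,
chosen to reflect the low-contrast regime that makes vessel segmentation
hard in practice.  At this level a global intensity threshold (Otsu) plus
the small-component filter — the classical baseline `baseline_segment()` —
reaches a Dice around 0.45, while on noiseless phantoms it recovers the
mask essentially exactly (the generator's sanity floor).  A trained network
must therefore use spatial context, not just intensity, to win; that gap is
what the end-to-end test measures.

What the phantoms do *not* emulate: branching tree topology, calibre
tapering, intensity inhomogeneity fields, anatomy-correlated background
structures, and the 3D connectivity that the component filter exploits in
real angiography.  Passing the phantom suite therefore demonstrates that
the architecture, losses, gradients and pipeline function as specified —
not that clinical-grade accuracy transfers to real data.

## Evaluation and post-processing

`metrics_report()` computes soft and hard Dice (the hard threshold defaults
to 0.5 and both variants are reported, since reported Dice values rarely
state which is meant), mean IoU over {background, vessel}, sensitivity,
specificity, accuracy, and AUC as the Mann–Whitney statistic (equal to
trapezoidal ROC integration).  Degenerate denominators return flagged
undefined values rather than silent zeros; empty classes are excluded from
the mean IoU with a warning.

`remove_small_components()` deletes connected components smaller than
0.03% of the total foreground (8-connectivity by default — vessels are
thin diagonals; 4-connectivity available).  The filter is idempotent:
surviving components still clear the threshold recomputed on the filtered
mask.  Here it runs per 2D slice; in volumetric angiography the same rule
is applied to the 3D vasculature, a documented divergence since 3D is out
of scope.

## Problem sizes used in the shipped checks

The end-to-end check trains the test preset (2 stages from width 8; 43,494
parameters) on 128 seeded 64 x 64 CTA-style phantoms for 30 epochs —
corpus, schedule and seeds fixed once — and evaluates on 32 fresh phantoms;
these sizes give a stable learning signal for a CPU-scale run.  The full
full-scale recipe (4 stages from width 64, 200 epochs, 96 x 96 patches,
512 x 512 slices) is encoded as `preset = "paper"` in both
`dnlnet_config()` and `train_config()` and runs the same code paths.

## Known limitations

* Single-device, single-precision-free (double throughout), CPU training
  only; no mixed precision or distribution.
* The multi-class softmax head is config-gated but unvalidated.
* DICOM reading is not implemented; convert slices to PNG/TIFF/JPG first.
* The 200-step single-phantom overfit probe in the test suite runs at a
  near-constant learning rate of 3e-3 — a notch above the training recipe,
  as is usual for capacity checks; under the decaying 1e-3 recipe the same
  probe needs more steps to cross the 0.05 loss mark.
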