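---
title: "mtloca: model, phantoms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mtloca: model, phantoms, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mtloca)
```

This vignette is the package's methods account: the model and its
assumptions, what the synthetic phantoms do and do not emulate, the tunable
parameters, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

The network maps a two-channel 128×128 input (intensity + edge magnitude)
to a binary lesion mask and a three-way class decision (normal / benign /
malignant), trained jointly.

**Backbone.** A three-level U-Net with residual blocks. Each encoder level
is Conv2D(3×3, zero padding) → GroupNorm → ReLU with a 1×1 projection
shortcut, followed by 2×2 max pooling; the symmetric decoder levels are
bilinear ×2 upsampling → skip concatenation → the same residual block.
Channel widths double per level (base `B`, 2`B`, 4`B`; bottleneck 8`B`), and
a final 1×1 convolution fuses the last decoder output into the per-pixel
representations `x_i` with `2B` channels, at **stride 1** so they align
with the 128×128 mask. Defaults: `B = 32` (full scale), GroupNorm with 8
groups, <5M parameters.

**Object-contextual attention.** A learned 1×1 projection of `x_i` yields
K = 2 raw soft-region scores per pixel; these raw maps are the coarse
segmentation logits that receive the auxiliary supervision. For region
pooling each score channel is softmax-normalized **across pixels**, so the
region representation `f_k = Σ_i d_k^i x_i` is a convex combination of
pixel features (the raw formulation is a bare weighted sum; normalizing
over pixels follows the object-contextual-representation convention this
head derives from, and the choice is isolated in `pixel_softmax()`).
Pixel–region compatibility is a scaled dot product between 1×1-transformed
queries (from `x_i`) and keys (from `f_k`), softmaxed over the K regions —
row-stochasticity is asserted in test mode. Contextual features
`y_i = δ(Σ_k w_ik H(f_k))` use `H` = linear + ReLU on the region vectors
and `δ` = 1×1 conv + GroupNorm + ReLU on the mixed map; `y` is concatenated
with `x` and passed through a 1×1 head to the final two-channel
segmentation logits. Ties in the per-pixel argmax break toward background.
Whether the original compatibility score was a dot product or additive
attention is unstated; scaled dot-product was chosen as the field default.

**Classifier.** Global average pooling over pixels, then a two-layer MLP
(hidden width 128, ReLU) ending in three neurons ordered
(normal, benign, malignant). Three wirings are supported, matching the
ablation arms: `no_oca` (no attention head; a 1×1 conv on `x` produces the
mask and the classifier pools `x`), `cls_from_oca` (classifier pools the
attention head's features), and `cls_from_backbone` (the proposed wiring:
attention refines segmentation while the classifier pools backbone
features).

**Loss.** `total = l_s + l_c` with `l_s = α·l_soft + l_aug`, α = 0.4;
`l_soft` supervises the raw soft-region maps, `l_aug` the final
segmentation logits, `l_c` the class logits — all mean cross-entropies. At
stride 1 the soft-region supervision target is the mask itself. The
`no_oca` arm has no soft maps; its `l_soft` is 0.

## Preprocessing

Inputs are converted to grayscale (Rec.709 weights), resized to 128×128
(bilinear; nearest-neighbour for masks so they stay binary), and augmented
with the Gaussian-derivative magnitude channel
`m = sqrt(g_x² + g_y²)`, where `g_x`, `g_y` are convolutions with the
partial derivatives of a 2D Gaussian. Choices the published description
leaves open:

- **σ = 1.5 px** (configurable), kernel truncated at 4σ: at 128×128 this
  emphasizes lesion-scale boundaries over speckle grain. The 4σ truncation
  leaves ≈3×10⁻⁵ of the kernel mass outside; tests account for this floor.
- **Reflect padding** for these convolutions (avoids spurious border
  response). Network convolutions use standard zero-padded Conv2D.
- The magnitude channel is **rescaled by its per-image maximum** before
  stacking, so both channels share the [0, 1] range.

Training-time augmentation: rotation uniform in (−45°, 45°), independent
horizontal/vertical flips (p = 0.5 each), center crop with p = 0.5
retaining 80% of the side then resized back, and random gamma in
[0.7, 1.4] on the intensity channel only. All geometric transforms are
composed into a single inverse affine map and applied in one resampling
pass (bilinear with edge fill for channels; nearest with zero fill for the
mask), so masks stay binary and are never touched by the contrast
transform.

## The phantom generator

The generator emulates the *composition* of a three-class clinical BUS
dataset, not its image physics. Each sample is a 128×128 image in [0, 1]:

- **Background**: constant mean level 0.45.
- **Benign**: a smooth hypoechoic ellipse; semi-axes drawn from [9, 24] px,
  axis ratio ≤ 1.8, random orientation; intensity drop (contrast) 0.45.
- **Malignant**: a spiculated region with radial boundary
  `r(θ) = r0 + a·P(θ)`, where `P` is a random-phase sum of integer
  harmonics (3…9) normalized to max |P| = 1; `r0` ∈ [10, 22] px, amplitude
  a = 5 px, contrast 0.65. Because the harmonics integrate to zero, the
  enclosed area is ≥ π r0² and ≤ π (r0 + a)², which the tests verify by
  pixel counting; the spiculation measurably raises the boundary shape
  factor `perimeter²/(4π·area)` above the benign range.
- **Normal**: background only, all-zero mask (the class⇔mask rule is
  checked exhaustively per dataset).
- **Speckle**: per-pixel Rayleigh draws normalized to mean 1, blurred with
  a small Gaussian (σ = 0.7 px) to mimic spatial correlation, then
  standardized to mean 1 and relative sd 0.18 — so the relative intensity
  variance in homogeneous regions matches the configured level (tested
  within 20% on ≥10⁴ pixels). Lesions are darker than background before
  speckle (hypoechoic), and the default class mix follows the published
  437 benign / 210 malignant / 133 normal composition.

Defaults were fixed once, as plausible desk-scale stand-ins, before any
acceptance measurement. What the phantoms do **not** emulate: acoustic
shadowing and enhancement, log-compression of the B-mode signal, depth
dependence, probe artifacts, anatomical context, or the intra-class
appearance diversity of real lesions. A green training surrogate therefore
establishes that the implementation can learn this family of
segmentation/classification problems end-to-end — not that it reproduces
clinical-scale performance.

## Training protocol and scales

Full scale mirrors the published protocol: Adam with initial learning rate
1e-3, batch 16, 400 epochs, stratified 5-fold cross-validation; no
learning-rate schedule, weight decay or early stopping (none are described;
all are deliberately absent, and the evaluation set is the held-out fold —
no separate blind split is described). Every random draw (weight
initialization, fold split, batch order, augmentation) derives from one
seed through a splitting hash, so runs are bit-reproducible on a given
machine (the float32 BLAS kernels are CPU-dispatched, so exact training
trajectories are machine-specific even at a fixed seed).

The **desk profile** (`desk_profile()`) exists so the whole pipeline runs
on one CPU: backbone width 8 with fused feature width 32, 30 epochs,
batch 4, 60 phantoms. Width 8 (over a nominal 16) fits the compute budget.
Two desk-specific convergence choices came out of diagnosing the
classification head, which at batch 8 spent a quarter of the epoch budget
stuck at the random-guessing plateau (GroupNorm removes per-image
brightness/contrast from the pooled features, so class evidence only
emerges once the backbone's spatial features differentiate — and 180 Adam
steps were too few): batch 4 doubles the optimizer steps within the same
30 epochs, and the 4x-base fused width enriches the pooled classifier
input. Held-out Dice saturates (≈0.9) by epoch 15; classification
accuracy needs the full 30 epochs on some seeds.

## Numerical and implementation choices

- No deep-learning runtime is available in the target environment, so all
  forward/backward passes are implemented natively. Convolutions run as
  stacked-shift BLAS `sgemm` kernels in **float32** (gradient noise from
  single precision is orders of magnitude below SGD noise); everything
  else is double. The fused C++ ops are tested against compositions of
  plain double-precision reference ops, the convolution against a
  triple-loop oracle, and full-model gradients against directional finite
  differences (pointwise finite differences are meaningless under float32
  forward noise).
- GroupNorm uses ε = 1e-5; statistics are per image and channel group, so
  batched and single-image forwards agree (tested).
- Attention scores are checked finite and surfaced as an error rather than
  clipped; cross-entropy clamps probabilities at 1e-12 only inside `log`.
- Segmentation argmax ties break toward the background class,
  deterministically.
- Predictions are reconciled across heads: the data's class-mask rule
  (normal ⟺ empty mask) is enforced on the joint output, so an image
  classified normal yields an empty mask. Without this, a handful of stray
  false-positive pixels on a truth-empty image (a few hundredths of a
  percent of its area) zeroes that image's Dice under the one-empty-mask
  convention — a discontinuity that dominated the variance of desk-scale
  Dice averages. Lesion-class predictions are never altered.
- Dice/IoU convention: both masks empty → 1 (correct normal predictions
  are not penalized); exactly one empty → 0. Segmentation metrics are
  averaged per image then across images; confusion matrices pool across
  folds by summation. Whether the published averages include normal
  (empty-mask) images is unstated — this convention is ours and is applied
  consistently.
- Grad-CAM: with a GAP + MLP classifier the class-score gradient at the
  feature layer is spatially constant, so the gradient-weighted activation
  map reduces exactly to a closed-form channel weighting; maps are
  ReLU-ed, max-normalized, and returned at 128×128.
- The acceptance worked-example targets recompute per-class F1 from the
  published precision/sensitivity pairs. One cell (three-class dataset,
  malignant row) cannot round-trip the printed table exactly: the printed
  inputs give F1 = 0.8969 → 0.897 while the table prints 0.896, consistent
  with the original computation using unrounded rates. The check therefore
  accepts one unit in the third decimal.

## Known limitations

- Phantom realism is intentionally minimal (see above); absolute
  clinical-scale scores are out of scope without the external datasets and
  GPU-scale training.
- The desk-scale ablation is a 60-image, single-fold comparison; its
  ordering check is a directional surrogate with a 1-Dice-point tolerance,
  not a reproduction of the published ablation margins. At this scale the
  classification-from-attention wiring trains noticeably less stably than
  the other two arms (classification gradients pass through the attention
  head and can disturb its segmentation features within the short epoch
  budget), and individual training runs occasionally fail to separate
  benign from malignant; both surrogate criteria are therefore genuinely
  stochastic at desk scale.
- K is configurable in the attention module but the shipped pipeline is
  binary-segmentation only; multi-scale context is out of scope.
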