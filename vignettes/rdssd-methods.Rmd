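---
title: "Methods: dual-branch RGB-D single-shot detection and highlight removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-branch RGB-D single-shot detection and highlight removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, the numerical choices, and the design
decisions that were genuinely open. It states no empirical result that the
test-suite or `scripts/acceptance.R` do not themselves compute.

## 1. The detection model

### Problem

Tomato plants bear fruit over a long period, so one plant simultaneously
carries green, orange and red fruit; green fruit are nearly the colour of
the canopy, and dense growth occludes fruit behind leaves and other fruit.
The task is six-way detection: maturity (green / orange / red) crossed with
occlusion state, labels `tomato1` … `tomato6` where odd ids are
non-occluded and even ids occluded. A registered depth map supplies
geometric boundary information that survives exactly the conditions (colour
camouflage, partial cover) under which the colour channel fails.

### Dual branches and decision-level fusion

Each modality gets its own VGG16-style SSD trunk: colour input 3×300×300,
depth input 1×300×300 (the branches differ only in the first layer's input
channels). Six taps form the feature pyramid — conv4_3, conv7 (the dilated
conv6/conv7 pair standing in for the fully-connected layers), and the
conv8–conv11 extras — with spatial sizes 38, 19, 10, 5, 3, 1. Feature maps
are recursively defined, `C(n) = f(C(n−1))` with `C(0)` the input image,
and the pyramid is their union across the six scales.

Fusion is at decision level: each branch keeps its own detection heads, and
the two prediction lists are concatenated (colour first) over the fused
prior set `B_all = B_rgb + B_depth`, 8,732 + 8,732 = 17,464 rows. Late
fusion was chosen because both branches' outputs share one representation
(scored boxes over priors), which makes the fusion a concatenation rather
than a learned alignment; it also lets the colour-only and depth-only
models fall out of the same code path (`mode = "rgb" / "depth" / "fused"`),
mirroring the three-model comparison design.

### Prior-box geometry

The six detection layers use the fixed pixel-size schedule 30/60, 60/111,
111/162, 162/213, 213/264, 264/315 with aspect-ratio menus {1,2,1/2} or
{1,2,3,1/2,1/3} — 4, 6, 6, 6, 4, 4 boxes per location. Per cell the menu
is: a square of side `min_size`; a square of side
`sqrt(min_size·max_size)` (the geometric mean is the conventional
second-square choice and is consistent with the paired size columns); and a
rectangle pair `(s√r, s/√r)`, `(s/√r, s√r)` per ratio r > 1. Centres sit at
`(a + 0.5)/|f_k|`; all coordinates are normalised and clamped to [0, 1].

A linear scale rule `s_k = s_min + (s_max − s_min)(k − 1)/(m − 1)` with
endpoints 0.2/0.9 is also part of the method's description, but with m = 6
it yields pixel scales 60…270, which contradicts the printed per-layer
schedule above. We treat the printed schedule as authoritative — it is the
canonical 300-input schedule with a special-cased first layer — and expose
the linear rule as its own operation (`scale_fraction()`), tested on its
own terms. The feature-grid-to-image mapping mixes its two cell indices in
the original description (the same index appears in both x and y minima);
we use consistent per-axis indices.

### Matching, loss, inference

A prior is positive iff its best IoU against the ground truths is strictly
greater than 0.5; additionally every ground truth claims its single
best-IoU prior. The forced-best rule goes beyond the bare threshold but
without it a small fruit can receive zero positives and the per-image loss
normaliser N becomes 0; it is the standard resolution. IoU uses continuous
areas `(x_max − x_min)(y_max − y_min)` with the intersection clamped at
zero — no ±1 pixel convention.

The objective is `F = (C_loss + α·L_all_loss)/N` with α = 1 (the
description sums the terms unweighted; α is exposed for completeness).
`C_loss` is softmax cross-entropy over positives plus the hardest
background priors at a 3:1 negative:positive ratio; `L_all_loss` is
smooth-L1 between predicted offsets and targets encoded in the standard
SSD parameterisation (centre deltas scaled by prior size and variance 0.1,
log size ratios scaled by variance 0.2 — the offset parameterisation is not
specified by the method description, so the canonical one is used).
`N = 0` yields zero loss rather than a division by zero. Inference decodes
all rows, filters by class probability, and applies per-class greedy NMS
(threshold 0.45, top-k 200 — canonical defaults, configurable).

### Refinement (Inception-style) block

The modified multi-scale block factorises one 3×3 into 1×3 followed by 3×1
(identical receptive field, 3) and widens another path with a dilation-2
3×3 (receptive field 7 where two stacked plain 3×3 give 5). The analytic
recurrence (`receptive_field()`) is cross-checked in the tests against an
empirical gradient-support probe. Where the block sits in the trunk is not
specified; we provide it as an optional shape-preserving drop-in appended
to the conv8/conv9 extras (`network$use_inception_extras`), off by
default, with its own unit tests.

## 2. Paired augmentation

The eight named stages run in order: ToSensor, PhotometricDistort, Expand,
RandomSampleCrop, RandomMirror, ToPercentCoords, Resize(300),
SubtractMeans. Only the stage names are part of the method's description;
all parameters (jitter ranges, expand max-ratio 4, the crop minimum-IoU
menu {0.1,…,0.9}, mirror probability 0.5) follow the canonical SSD recipe
those names denote. Two readings of "augmented with eight transformed
versions" exist; we implement the composed 8-stage pipeline as primary and
provide `expand_dataset()` (materialise k augmented copies) for the other
reading. The stage list mentions no rotation even though a summary sentence
does; we implement the named list only.

Decisions: photometric distortion never touches the depth channel (depth
is geometry, not photometry); the depth fill value for expand padding is
the scene's far value (background is far); depth is scaled to [0, 1] by the
configured near/far range before its mean is subtracted (the description is
silent on depth normalisation); channel means default to the training
split's means since no mean values are printed.

## 3. The synthetic world

No accession of the original greenhouse data exists, so the generator is a
stated world, not a fit to data. It emulates a Kinect-V2 registered pair:

* canvas 512×424 (the depth sensor's grid) with depths in 500–4500 mm,
  background at far;
* 2–6 fruits per scene, radii 28–60 px, rendered as ellipses (axis jitter
  ±15 %) with maturity-dependent hue bands — green 90–140°, orange 20–40°,
  red 0–15° (HSV) — radial shading, and spherical depth blobs protruding
  toward the camera;
* irregular green occluders (unions of 3–5 ellipses) targeting a random
  fruit at strictly nearer depth, at an expected 0.5 occluders per fruit;
* z-buffered rendering throughout, so fruit–fruit overlap also occludes;
* optional additive elliptical-Gaussian specular highlights with the
  per-pixel added intensity kept as the ground-truth mask.

The occlusion label threshold — the covered-area fraction above which a
fruit is labelled occluded — is nowhere defined in the method's
description; we chose 0.10 once (small enough that clearly visible partial
occlusion counts) and expose it in `scene_config()`. Labels are recomputed
from the rendered z-buffer, so they are consistent with the pixels by
construction, and the tests re-derive every label from the kept fruit
masks.

What the generator does *not* emulate: real foliage texture and colour
statistics, sensor noise and depth shadows/invalid pixels, registration
error between the channels, fruit clusters with specular inter-reflection.
A green end-to-end test therefore establishes that the pipeline can learn
and evaluate the 6-way task on geometrically faithful scenes — not that it
reaches any particular accuracy on greenhouse imagery.

## 4. Training at desk scale

The reference hyperparameters (batch 8, learning rate 1e-3, Adam,
evaluation every 500 iterations, 120,000 iterations) are the configuration
defaults. They are far beyond a CPU session, so the smoke test trains a
width-reduced model: `width_multiplier = 1/32` scales every channel width,
batch 4, evaluation every 20 iterations, at most 500 iterations with early
stop at training mAP 0.9 on the 8 training scenes. Stochastic augmentation
is disabled for this overfit check (it is exercised by its own tests);
with it enabled the same run converges more slowly. The headline mAP
values of the original three-model comparison require the real dataset and
full-scale GPU training and are deliberately not reproduced; the
group-aggregation arithmetic that links the per-class and group tables is
checked exactly instead.

The built-in engine computes convolutions by im2col + GEMM (Armadillo),
with hand-derived backward passes verified against central finite
differences at 1e-9 … 1e-11 agreement in the unit tests. Numerical
choices: He-normal initialisation; cross-entropy clamps probabilities at
1e-12; Adam (β₁ 0.9, β₂ 0.999, ε 1e-8); ties in NMS and AP ranking broken
by input index (stable).

## 5. HRGAN

The generator carries a recurrent attention module: N recursive blocks,
each consuming the input image concatenated with the previous intensity
mask (initialised to the constant 0.5), passing through a small residual
feature module into a convolutional LSTM with per-channel peephole
connections (the five gate equations are implemented exactly and tested
against a scalar hand computation), and emitting a refined mask through a
sigmoid head. A removal head maps (image, final mask) to the highlight-free
estimate. The discriminator is a strided conv stack with a global-average
sigmoid score.

Losses: `L_M = Σ β_i · MSE(M_i, T_i)` with `β_i = 0.5^{N−i+1}` (so
β_N = 0.5 and Σβ = 1 − 0.5^N); `L_P` an MSE between features of an
injected, frozen extractor — a fixed-seed untrained conv net here, since no
pretrained backbone is available offline, with the extractor injectable for
users who have one; `L_Adv = E[log D(I_f)] + E[log(1 − D(G(I_h)))]`, the
discriminator maximising it and the generator minimising the non-saturating
complement `−E[log D(G(I_h))]`; `L_T = L_M + L_P + L_Adv` unweighted.

Open points resolved here: the method narrative says "unpaired training
data", but `L_M` and `L_P` both require ground truth; we train
supervised-plus-adversarial on synthetic pairs and note the contradiction.
N (the block count) is never stated; default 4, configurable. Per-block
truths `T_i` are the ground-truth mask resized to each block's resolution
(all blocks are full-resolution in the default generator, so `T_i = T`).
HRGAN is exposed as an optional preprocessing stage and is off by default
in the detection pipeline.

## 6. Known limitations

* The engine is single-threaded and desk-scale; full-width 300-input
  training is possible but impractically slow in R.
* The synthetic world's colour statistics are simple; photometric
  robustness conclusions do not transfer to field imagery.
* The AP protocol is all-point interpolation by default (the method's
  description never states one); VOC-2007 11-point is available via
  `interpolation = "11point"`.
* Whether the printed maturity/occlusion group numbers are means of class
  APs or re-evaluations on merged labels is ambiguous; the printed
  occlusion value equals the class-AP mean to 4 decimals, so the mean is
  the default and merged re-evaluation is provided as `group_mode =
  "merged"`.
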