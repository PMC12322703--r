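---
title: "Methods: background-suppressed multi-scale detection of wild licorice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: background-suppressed multi-scale detection of wild licorice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Three licorice species (*Glycyrrhiza uralensis*, *G. glabra*, *G. inflata*)
grow wild in arid rangeland, interleaved with weeds whose color and texture
closely resemble them. UAV surveys produce very large frames (e.g.
8192×5460 pixels) in which individual plants span anything from a dozen to
a few hundred pixels. Detection is hard for three reasons this package's
architecture addresses directly: cluttered vegetated backgrounds
(background suppression), large within-class scale variation (multi-scale
extraction), and high inter-class similarity (fine-grained feature
fusion).

`alpdnet` implements the complete framework: the data pipeline (tiling,
YOLO label I/O, 8:1:1 splitting, box-aware augmentation), a synthetic
scene generator so every stage is testable without field data, the
detector itself (a ResNet34-derived backbone with three bespoke modules),
a seeded SGD trainer with early stopping, the evaluation stack
(precision, recall, mAP50, mAP50-95, F1-confidence and P-R curves,
Grad-CAM), and a per-layer FLOP accountant.

## Architecture

The network is a single-stage anchor-free detector:

* **Backbone (ResNet-AL).** ResNet34 layout: a 7×7 stride-2 stem plus
  3×3 stride-2 max-pool, then stages of 3/4/6/3 BasicBlocks at widths
  64/128/256/512. Every BasicBlock carries an **ABSM** on its residual
  branch (before the addition, the squeeze-excitation convention), and
  one **LMSM** follows each stage. The pyramid taps are the outputs of
  stages 2/3/4 at strides 8/16/32 — feature maps `c`, `b`, `a`.

* **ABSM (adaptive background suppression).** A depthwise 7×7
  stride-2 convolution compresses the map; multi-head self-attention
  *across channel tokens* (each channel embedded as its flattened
  compressed response, queries/keys/values from depthwise 7×7
  projections) computes channel similarity; global pooling plus a
  channel softmax yields weights, and the input is rescaled by
  `C * weight` so uniform attention is exactly the identity. The spatial
  stage pools per-pixel channel mean/max statistics into horizontal and
  vertical profiles, refines them with a shared 1-D convolution,
  collapses each to one channel, and gates the map with the outer
  product of the two sigmoid profiles — the classic coordinate-attention
  form. All projections are bias-free, which makes the module's
  zero-weight behaviour exactly `0.25 * x` (two sigmoid gates at 0.5)
  and testable in closed form.

* **LMSM (lightweight multi-scale module).** A channel branch (local
  2×2 then global average pooling, a kernel-3 1-D convolution along the
  channel axis, broadcast restoration) gates a multi-scale branch (1×1
  reduction, four channel slices through 3×3 convolutions at dilations
  1/2/3/4 with padding = dilation, concatenation, 1×1 restoration):
  `out = branch2 * sigmoid(branch1) + x`. The residual identity under
  zeroed branch weights is a gradient-safety property the tests pin.
  "Anti-pooling" is implemented as broadcast restoration; true
  max-unpooling with switches would add state for no measurable benefit
  at this placement.

* **PFFM / WSAF (progressive fusion).** WSAF fuses two maps: the
  non-target operand is bilinearly resampled and 1×1-projected, the two
  are combined with learnable scalars `W1, W2` (init 1), a per-channel
  sigmoid gate of the pooled sum rescales and is added back
  (`z = g·F1 + F1`), and transformer-style multi-head self-attention
  over spatial tokens refines the result residually (`z + MHSA(z)`).
  The residual form is deliberate: a bare attention output would discard
  locality and break the zero-weight closed form. The neck computes
  `ab = WSAF(a, b)` and `bc = WSAF(b, c)` once and shares them:
  `A = WSAF(a, bc)` (stride 32), `B = WSAF(ab, bc)` emitted at stride 16
  by aligning the first operand onto the second (the head needs strides
  8/16/32, and the middle output belongs at the middle scale), and
  `C = WSAF(c, ab)` (stride 8) — five distinct units, independent
  parameters.

* **Head.** Decoupled, one per level: two parallel branches
  (classification / box), each two 3×3 conv-BN-ReLU layers and a plain
  1×1 convolution. Boxes are anchor-free ltrb distances in stride units
  made non-negative by softplus; scores are per-class sigmoids (no
  objectness branch — the architecture description names only two
  branches). Training assignment is center-inside-box with a 2.5-stride
  center radius and smallest-area tie-break; the loss is BCE over all
  cell-class entries plus `1 - CIoU` on positives, weighted 1:5 and
  normalized by the positive count. The loss design is the package's
  own: the source architecture specifies none.

## FLOP accounting and budget calibration

`count_flops()` builds a per-layer table analytically from the
configuration; `profile_model_flops()` traces a live forward pass and
must agree within 1% (a structural cross-check that the instantiated
network matches its configuration). The convention: 2 FLOPs per
multiply-accumulate, convolutions and projections only; attention costs
`2·(2·n_q·n_kv·d)`; pooling, normalization, activations and resampling
are free. Under this convention the plain ResNet34 baseline with the
decoupled head costs 72.9 GFLOPs at 640×640.

Several architectural constants are not fixed by the published
description; we calibrate them against the published per-stage
complexity budget (+2.7 G for ABSM across all 16 blocks, +0.1 G / +0.13%
for LMSM, +7.4 G for the fusion neck) and then freeze them:

* ABSM compression stride 2 with all depthwise projections at kernel 7
  (adds 2.78 G; stride 4 would add only ~0.5 G and starve the channel
  attention of embedding resolution);
* LMSM reduced width `width/16` capped at 16 channels (adds 0.098 G,
  a 0.13% relative increase over the ABSM model);
* WSAF KV token budget 340 (adds 7.37 G; a 400-token budget would
  overshoot at 8.0 G), with dense bias-free Q/K/V/O projections and
  1-D segment pooling of the flattened token sequence for keys/values;
* head branch widths (128, 160, 168) per level.

These four choices make the ablation chain land at 72.9 / 75.6 / 75.7 /
83.1 GFLOPs — and they were chosen for exactly that reason; the tests
treat the budget as a specification, not an observation.

## Training recipe

`alpd_train_config()` defaults to the published recipe: 640×640 inputs,
200 epochs, batch 8, SGD (lr 0.001, momentum 0.937, weight decay
0.0005), early stopping on validation mAP50 with patience 50, seed 0,
constant learning rate (a cosine option is provided but off by default).
No warmup and no mosaic/mixup: the pipeline uses exactly the four
augmentations (mirror, k·90° rotation, brightness, translation). The
best validation checkpoint is kept. Rotation is restricted to right
angles by default because arbitrary angles make axis-aligned boxes
loose; brightness factors are drawn from [0.6, 1.4] and translations
from ±20% of the image side, values typical for vegetation imagery;
the clipped-box keep threshold is 0.3 of the original area for both the
tiler and the translation operator.

## The synthetic scene generator

No public dataset accompanies the original study, so the package ships a
generator that emulates the *statistical* structure of the task: three
classes rendered as leaf rosettes distinguished by hue band, leaf count
and leaf aspect (the same kind of subtle cue that separates licorice
species), weed blobs whose hues overlap the class bands (hard
negatives), partial occlusion, radii spanning roughly 12-220 px at the
640 tile size, and a low-frequency sandy background with speckle.
Scenes are a pure function of `(seed, index)`. A plant is labeled when
at least 25% of its rendered area is visible, mirroring the tiler's
box-keep rule.

What the generator does **not** emulate: real radiometry, shadows,
perspective, plant morphology beyond rosettes, and annotation noise.
Passing the capability tests therefore demonstrates that the
architecture, loss, decoding and metrics form a working detector — not
that the published field accuracy is reproduced; that would require the
original UAV imagery and GPU-scale training, which are out of scope.

## Numerical and testing choices

* All numerics are double precision on a small reverse-mode autograd
  tape; convolution/pooling/resampling kernels are compiled C++ with an
  im2col-BLAS path for dense convolutions and a direct path for
  depthwise ones. Every operator is verified against central finite
  differences.
* Batch-norm uses batch statistics in training (biased variance in the
  normalizer, unbiased in the running estimate) and running statistics
  at inference.
* Bilinear resampling uses half-pixel centers; ties in channel-max
  statistics route gradients to the first maximizer.
* The CIoU aspect term treats its balancing coefficient as a constant
  during differentiation, the standard practice.
* Greedy NMS and greedy matching break score ties by order; AP uses
  all-points interpolation, and the test suite checks it against an
  independent brute-force oracle over every score cut.
* Capability checks run at reduced scale: the smoke test overfits 20
  easy 256×256 scenes with a width-reduced model (stage widths
  8/16/32/64, head width 16, KV budget 64 — all modules enabled), which
  the methods here treat as the standard problem size for CPU-scale
  verification.

## Known limitations

* The published description leaves several structural details open
  (attention geometry, loss, head widths, fusion alignment for the
  middle output); this package documents each choice above and marks
  the calibrated ones explicitly.
* The printed complexity formula for convolution cost is dimensionally
  inconsistent as published (its first term lacks the spatial factor);
  the accountant implements the standard convention stated above
  instead.
* Training in R on CPU is practical only at reduced scale; the full
  640-input, full-width recipe is provided for completeness and runs,
  but reproducing field-data accuracy is explicitly not a goal.
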