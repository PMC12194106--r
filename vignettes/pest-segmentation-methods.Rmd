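---
title: "Cross-attention TransU-Net for rice-pest segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-attention TransU-Net for rice-pest segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catransunet)
```

## The problem

Rice pests in field imagery are hard to segment: bodies span two orders of
magnitude in size, elongated pests carry one-pixel-thin legs and antennae,
many pests sit within a few percent of the background luminance, and the
background itself is cluttered vegetation. CATransU-Net addresses this with
a U-Net-shaped encoder-decoder whose three characteristic components each
target one failure mode: multi-scale dilated convolution for size
variation, bottleneck attention for long-range context, and cross-attention
skip fusion for recovering spatial detail without re-importing background
clutter.

This package implements the full architecture, its training and evaluation
protocol, and a synthetic scene generator, natively in R. The network runs
on a compact reverse-mode automatic-differentiation core (`R/autodiff.R`,
`R/ops.R`) whose convolution and normalization kernels are compiled C++
(`src/`); everything else is base R on BLAS matrix products.

## The model

**Encoder.** Four residual dilated Inception (RDI) stages, each followed by
2x2 max pooling. An RDI block runs four parallel 3x3 convolutions with
dilation rates 1, 3, 5 and 7 (effective extents 3, 7, 11 and 15 pixels),
each as Conv+BN with "same" padding equal to its rate so the branches stay
spatially aligned. The branches are concatenated (each carries a quarter of
the stage width), fused by a 1x1 Conv+BN, added to a 1x1 Conv+BN projection
of the block input, and passed through ReLU. Setting all rates to 1 gives
the plain Inception ablation variant; dropping the residual projection
gives the dilated-Inception variant; a plain double 3x3 convolution stage
gives the U-Net baseline.

**Bottleneck: dual Transformer attention (DTA).** The pooled stage-4
output is raised to the bottleneck width by a double 3x3 convolution, then
two attention branches act on the same features `F`:

* *TSA* (Transformer self-attention): 1x1-convolution projections give
  `Q, K, V` over the `n = h*w` flattened positions; the map
  `softmax(Q^T K / sqrt(d_k))` (row-wise over keys) aggregates `V`. A
  configuration switch (`attn_scale = "linear"`) selects the literal
  `/ d_k` scaling instead of `sqrt(d_k)`; the default follows the standard
  scaled dot-product form. Multi-head operation splits channels evenly
  (default one head).
* *GSA* (global spatial / position attention): one 1x1 convolution reduces
  `F` to `c' = c/8` channels; the flattened reduced map `Map1` and its
  transpose `Map2` form pairwise position logits `Map1 %*% Map2`,
  row-softmaxed into a position map (no scaling divisor), which aggregates
  a full-width 1x1-convolution value branch.

The branch outputs are fused by learned scalar gates initialized at zero:
`F_out = gamma1 * F_TSA + gamma2 * F_GSA + F`. At initialization the
bottleneck is therefore an exact identity, and the gates open only as the
attention branches become useful — which also means gradient flow to the
rest of the network is unimpeded from the first step.

**Cross-attention skip connections (CASC).** At each decoder stage the
up-sampled decoder map (queries) is fused with the same-resolution encoder
skip (keys/values). Both maps first pass a channel-selection gate: the
per-channel spatial mean is mapped by a learned `c x c` matrix through a
sigmoid, giving per-channel weights in (0, 1) that rescale the map. The
cross-attention map `softmax(Q^T K / sqrt(c))` aggregates the encoder
values; the attended map is concatenated with the decoder map and fused to
the stage width by 1x1 Conv+BN+ReLU. Because a full attention matrix at
the 256x256 skip would need a 65536^2 matrix, attention operates on an
average-pooled grid of at most `casc_grid` (default 32) cells per side and
the attended output is nearest-neighbour up-sampled back before
concatenation; the grid is configurable and stages at or below the grid
size use full-resolution attention.

**Decoder and head.** Each decoder stage is a 2x2 transposed convolution
(stride 2; a bilinear+1x1 switch is provided) followed, after skip fusion,
by a residual pair of 3x3 Conv+BN(+ReLU) layers. The printed order
Conv+ReLU+BN in the source material is implemented as Conv->BN->ReLU, the
standard arrangement the figure abbreviations are taken to mean. A 1x1
convolution and sigmoid produce the per-pixel pest probability map at the
input resolution.

## Capacity calibration

Stage widths are not stated by the architecture's published description;
the only quantitative capacity constraints are the published totals of
14.6 M parameters and 18.9 GFLOPs for one 256x256 forward pass. Those two
observables jointly pin the *slope* of the width family: parameters are
dominated by the deep, spatially small layers while FLOPs are dominated by
the shallow, full-resolution layers, so a standard doubling family cannot
satisfy both. The calibrated defaults, frozen in `default_config()`, are
stage widths 24/52/104/256 with bottleneck width 840, which the package's
own accounting reports as 14.60 M parameters and 19.1 GFLOPs. The FLOP
meter counts a multiply-accumulate as 2 FLOPs and includes convolutions,
biases, batch normalization (4/element), activations (ReLU 1, sigmoid
4/element), softmax (3/entry) and the attention matrix products as dense
GEMMs.

## Loss and training protocol

Training minimizes the mean per-pixel binary cross-entropy of the sigmoid
probabilities, computed from logits in the numerically stable softplus
form. The "balanced" option reweights foreground pixels by the
background/foreground ratio of the batch (`pos_weight = "balanced"`), or
by any fixed positive factor; it is off by default. The optimizer is Adam
(first-moment decay 0.9 — the stated "momentum" — second-moment decay
0.999) with learning rate 0.001, weight decay 0.0001 applied as an L2 term
in the gradient, mini-batches of 32 and 3000 iterations; iterations are
optimizer steps, matching a loss curve drawn against iteration count.
Convolution weights are Kaiming-initialized; normalization layers start at
identity; attention gates start at zero. When the monitored loss (a held
out 10% validation split by default, else the running training loss) fails
to improve for `plateau_patience` iterations (default 200), the learning
rate is multiplied by 0.1. Five-fold cross-validation splits are provided
(`five_fold_split`), seeded, with fold sizes differing by at most one.

After the optimization loop the batch-normalization running statistics are
recalibrated with one training-mode pass over the training tensors
(momentum 1), the "precise BN" finishing step: evaluation-mode
normalization then uses the statistics of the data the model was actually
fit on rather than an exponentially lagged average. On small datasets
trained at high learning rates the lag otherwise costs several Dice
points.

## Evaluation

Pixel-level precision `|SF∩GF|/|SF|` and recall `|SF∩GF|/|GF|` are
computed on pooled pixels at a 0.5 threshold. Average precision sweeps the
PR curve over all distinct scores, applies the monotone non-increasing
precision envelope and integrates over recall; per-class AP pools the
pixels of each class's samples, and mAP is the arithmetic mean over
classes. Empty-set conventions: an empty prediction has precision 1
against an empty ground truth and 0 otherwise; recall against an empty
ground truth is 1 for an empty prediction and undefined (NA) otherwise.
AP requires at least one foreground ground-truth pixel and raises an error
otherwise. Detection-style metrics with IoU-matched boxes are out of
scope — the evaluation is pixel-set based throughout.

## Synthetic scenes

The generator (`generate_pest_scene`) emulates the properties that matter
for this task, not photorealism:

* backgrounds: multi-octave value noise with oriented sinusoidal stripe
  fields (leaf venation), a soil-toned variant, and a cluttered variant
  with drawn grass blades and debris;
* pests: oriented capsules, segmented (three-ellipse) bodies, and winged
  silhouettes — three shape families that serve as class identities — with
  body length drawn from `pest_scale_range` (default 2-25% of the canvas)
  and aspect ratio from `body_aspect_range` (default 1.8-4);
* thin appendages: 1-pixel polyline legs/antennae attached at the body
  boundary (default 4-8 per pest);
* low-contrast mode places the pest luminance within ±10% of the local
  background; normal mode enforces a dark-bodied separation;
* occlusion: with probability `occlusion_prob` a grass blade is drawn over
  a pest and the occluded pixels are removed from the mask.

Masks record exactly the visible drawn pixels, so mask/geometry
consistency is testable analytically (a fixed-scale capsule's foreground
fraction is bounded by its closed-form area). Images are quantized to
8-bit levels at creation so a PNG round trip is bit-identical. Everything
is a pure function of `(params, seed)`; the dataset builder derives
per-scene sub-seeds from one master seed and reproduces the published
class-imbalance pattern (counts proportional to a 14-class distribution
with roughly 6:1 imbalance) for mAP exercises, with optional balancing by
the 14-variant augmentation bank (7 dihedral transforms, 4 photometric
jitters, 3 random crop-resizes). Preprocessing follows the published
pipeline: random 640x640 crop, resize to 256x256 (bilinear image,
nearest-neighbour mask so it stays binary).

What passing tests on these scenes do *not* show: robustness to real
field photography — specular leaves, depth-of-field blur, JPEG artefacts,
annotation noise, and pests whose texture (not just luminance) matches the
background are all absent from the generator.

## Desk-scale experiment sizes

The test suite exercises training at sizes chosen for a single CPU: the
memorization experiment fits a slim model (stage widths 12/24/48/96,
bottleneck 96, attention grid 16) to eight 128x128 scenes for 300
full-batch iterations at learning rate 0.003 with the balanced loss —
settings picked once as a reasonable small-data protocol (full-batch
gradients remove sampling noise on 8 samples; the higher rate compensates
for the small batch-normalization statistics). Architecture-accounting
checks build the full 14.6 M-parameter default; everything else runs on
tiny width families (8/8/8/16) where the contracts are size-independent.

## Numerical choices and degenerate inputs

* Attention logits are max-shifted before exponentiation; rows of every
  attention map sum to 1 to 1e-6 by construction.
* BN uses eps 1e-5, biased batch variance, running momentum 0.1.
* Max pooling routes gradients to the first maximal element on ties.
* The BCE loss validates binary ground truth and uses softplus forms; a
  non-finite training loss aborts with a diagnostic rather than silently
  continuing.
* `forward_pass` refuses inputs whose spatial size differs from the
  configured one — there is no silent resizing inside the model.
* Single-position attention (1x1 maps) degenerates to the identity weight
  1, and uniform logits give exact averaging; both are covered by tests.

## Known limitations

* CPU-only: a 256x256 forward pass of the full model takes a few seconds;
  training the full configuration at the published 3000x32 protocol is out
  of reach on one CPU and is not attempted — the published IP102/AgriPest
  accuracy numbers are not reproduced here.
* The pooled-grid cross-attention is an approximation forced by the
  quadratic memory of full-resolution attention; the architecture's
  published description does not address this, and results at shallow
  stages depend mildly on the grid size.
* The self-attention divisor, the position-map normalization axis, and
  the bottleneck fusion formula are implemented in their standard readings
  where the printed formulas are ambiguous or self-referential; switches
  are exposed where both readings are defensible (`attn_scale`).
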