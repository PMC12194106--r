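# catransunet

Per-pixel detection of rice pests in field images is hard for the usual
reasons crop imagery is hard: the pests range from a few pixels to a
quarter of the frame, their bodies are elongated with one-pixel legs and
antennae, many sit at nearly the background luminance, and the background
is cluttered vegetation. **catransunet** is a native R implementation of
CATransU-Net, a cross-attention TransU-Net for this task, aimed at
researchers in agricultural image analysis who work in R and want a fully
inspectable, CPU-trainable implementation of the architecture together
with its training protocol, evaluation metrics, and a synthetic scene
generator for controlled experiments.

## The model

CATransU-Net is a U-Net-shaped encoder-decoder with three characteristic
components:

* **RDI encoder** — four residual dilated Inception stages; each runs four
  parallel 3×3 convolutions at dilation rates 1/3/5/7 (effective extents
  3–15 px), concatenates them, fuses with a 1×1 Conv+BN and adds a 1×1
  Conv+BN residual projection, then ReLU. Each stage is followed by 2×2
  max pooling.
* **DTA bottleneck** — dual Transformer attention on the deepest features
  `F`: a self-attention branch `TSA = softmax(QᵀK/√d_k)V` over the
  flattened positions, and a position-attention branch (GSA) whose map is
  the row-softmax of `Map₁Map₂` built from a c → c/8 channel reduction,
  applied to a full-width value branch. The output is the gated residual
  `F' = γ₁·TSA(F) + γ₂·GSA(F) + F`, with γ₁ = γ₂ = 0 at initialization so
  the bottleneck starts as an exact identity.
* **CASC skips** — each decoder stage queries the same-resolution encoder
  skip by cross-attention: both maps are channel-gated
  (`A = sigmoid(W·P)`, `P` the per-channel spatial mean), the decoder map
  provides Q and the encoder map K/V, and the attended encoder features
  are concatenated with the decoder map and fused back to the stage width.
  Attention runs on a pooled grid of at most 32×32 cells for memory
  feasibility.

The decoder uses 2×2 transposed convolutions and residual 3×3 Conv+BN+ReLU
pairs; a 1×1 convolution + sigmoid yields the probability map. Training is
Adam (lr 0.001, weight decay 0.0001, β₁ = 0.9, batches of 32, 3000
iterations, reduce-on-plateau ×0.1) with balanced binary cross-entropy and
Kaiming initialization; evaluation is pixel-level precision/recall, AP
over score thresholds, and mAP across classes.

The default configuration (stage widths 24/52/104/256, bottleneck 840) is
calibrated so the whole network carries **14.60 M trainable parameters**
and **19.1 GFLOPs** per 256×256 forward pass under the
multiply-accumulate-×2 convention.

Everything runs on a compact reverse-mode autodiff core written for this
package (R on BLAS, with Rcpp/Armadillo kernels for convolution and the
fused elementwise loops) — there is no external deep-learning framework
underneath.

## Worked example

Generate a small synthetic dataset, train a slim model, and evaluate it:

```r
library(catransunet)

styles <- c("leaf_stripes", "soil_texture", "clutter")
scenes <- lapply(1:8, function(i)
  generate_pest_scene(scene_params(canvas_size = 128L,
                                   background_style = styles[(i - 1) %% 3 + 1],
                                   class_id = (i - 1) %% 3 + 1),
                      seed = 100 + i))

model <- build_model(model_config(stage_widths = c(12, 24, 48, 96),
                                  bottleneck_width = 96,
                                  input_size = 128, casc_grid = 16),
                     seed = 1)
fit <- train_model(model, scenes,
                   train_config(learning_rate = 0.003, batch_size = 8,
                                total_iterations = 300, val_fraction = 0,
                                pos_weight = "balanced", seed = 1))
print(fit)
#> CATransU-Net fit: 300 iterations, loss 1.6123 -> 0.0038 (final lr 0.003)

report <- evaluate_model(model, scenes)
print(report)
#> Pixel-level evaluation (8 samples, threshold 0.50)
#>   precision: 1.0000   recall: 1.0000   mAP: 1.0000
#>   AP per class: 1=1.000  2=1.000  3=1.000
```

The fit memorizes the eight training scenes exactly (Dice 1.0 at
threshold 0.5): the per-pixel loss falls from 1.61 to about 0.004, and
pooled precision/recall over the training pixels reach 1.0. On held-out
scenes a model this small trained this briefly will of course do far
worse — the example demonstrates the optimization path and the metric
plumbing, not generalization.

Architecture accounting for the full configuration:

```r
m <- build_model(default_config())
count_parameters(m)$total_params / 1e6   # 14.60 (millions)
estimate_flops(m, 256)                   # 19.15 (GFLOPs at 256x256)
```

A thin command-line interface over the same functions ships in
`inst/cli/pestseg.R` (`synth`, `train`, `eval`, `predict`, `ablate`,
`report` subcommands).

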