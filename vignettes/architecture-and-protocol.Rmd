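---
title: "A lightweight attention-ghost classifier for field plant-disease images: model, counting conventions and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Architecture and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(leafcga)
```

## The problem this package addresses

Recognising crop diseases from photographs taken *in the field* differs from
laboratory benchmarks in two ways: the images are corrupted by soil
backgrounds, weather and occlusion, and the models must run on low-power edge
hardware (single-board computers), which caps the parameter and FLOP budget.
`leafcga` implements a family of lightweight convolutional classifiers built
around three ideas — attention-augmented asymmetric downsampling
(CBAM-ADown), ghost-convolution cross-stage blocks (C3Ghost), and a
four-branch multi-scale pooling fusion block (AFC-SPPF) — together with the
data-augmentation, cross-validation and export machinery needed to train and
deploy them. The package is parameter-exact: every block's trainable-parameter
count closes in integer arithmetic against the reference totals this design
is calibrated to, and the test suite asserts those identities.

The neural-network engine itself (convolution, pooling, batch normalisation,
backpropagation, Adam) is part of the package, written in R with
RcppArmadillo kernels. Since the contribution re-implemented here *is* the
architecture arithmetic, owning the engine keeps every convention (bias
handling, padding, counting) explicit and testable.

## Blocks and parameter conventions

All convolutions are **bias-free and followed by batch normalisation**, and
all activations are SiLU. This is the only convention under which the
reference parameter totals are reproduced exactly; it is also the standard
convention of the model family the baseline comes from. A
convolution-BN-SiLU unit with kernel $k$ therefore has
$k^2 c_{in} c_{out} + 2 c_{out}$ trainable parameters.

* **C2f** (baseline stage block): 1×1 projection to $c$, split into two
  halves of width $h = c/2$, $n$ shortcut bottlenecks (two 3×3 convolutions
  at width $h$ with identity shortcut), 1×1 fusion from $(2+n)h$.
* **ADown**: a 2×2 stride-1 average pool, channel split into halves; one
  half through a 3×3 stride-2 convolution, the other through a 3×3 stride-2
  max pool and a 1×1 convolution; concatenation (convolution branch first —
  the order is fixed and tested). Parameter count
  $9\frac{c_{in}}{2}\frac{c_{out}}{2} + \frac{c_{in}}{2}\frac{c_{out}}{2} + 2 c_{out}$.
* **Ghost convolution**: half the output channels from a dense $k\times k$
  convolution, the other half from a cheap 5×5 depthwise convolution of the
  first half. **C3Ghost** wraps ghost bottlenecks (down to quarter width and
  back, no activation on the second ghost unit, identity shortcut) in a
  cross-stage pair of 1×1 projections with a 1×1 fusion.
* **AFC-SPPF**: four parameter-free branches at the input resolution —
  identity, the *final* output of three cascaded $k\times k$ stride-1 max
  pools, a 3×3 and a 5×5 stride-1 max pool — concatenated to $4c$ and fused
  by a 1×1 compression convolution + BN and a 3×3 depthwise convolution +
  BN (SiLU after each). Parameter count $4c^2 + 13c$.

Three structural choices in AFC-SPPF were genuinely open and were fixed by
the parameter arithmetic:

1. the main branch contributes only the final cascade output (a wider
   concatenation would break the $4c^2$ term);
2. the post-processing is one depthwise convolution *without* a pointwise
   follower — the "depthwise separable" wording is ambiguous, and only the
   depthwise-only reading yields the $13c$ affine/BN/depthwise term that
   matches all four placement deltas;
3. the branch pools are max pools (parameter counts cannot distinguish max
   from average; max mirrors the SPPF lineage).

The "adaptive" size guard is implemented as a parameter-free adaptive max
pool applied only when a branch's spatial size drifts from the input's; with
odd kernels and same-padding it never triggers, which satisfies the stated
size-consistency goal at zero cost.

Padding is $k\,\mathrm{div}\,2$ everywhere and odd feature maps
floor-divide under stride 2.

## Attention variants

Five attention mechanisms attach to ADown, one instance per branch, each
attending the branch output at $c_{out}/2$ channels (placement on the branch
*output* is a package choice; with the doubling widths used by every stage,
pre- and post-convolution placement give identical counts, and gating what
each branch produced is the cleaner reading). Their parameter conventions
were reverse-fixed from the per-module reference deltas and are asserted
cell-by-cell in the tests:

| kind | structure | parameters at width $c$ |
|------|-----------|------------------------|
| CBAM | shared bias-free MLP ($c \to c/16 \to c$) over avg+max descriptors; 7×7 bias-free spatial conv over mean/max maps | $2c\lfloor c/16\rfloor + 98$ |
| SE | bias-free MLP over the avg descriptor | $2c\lfloor c/16\rfloor$ |
| ECA | 1-D conv over the channel descriptor, adaptive odd kernel $k(c)$ | $k(c)$ |
| SimAM-style | parameter-free energy gating | $0$ |
| GAM | per-position MLP ($c \to c/4 \to c$, biased) + two biased 7×7 convs with BN | closed form in the code |

The per-module counts are authoritative. Six of the whole-model reference
totals for attention variants (and two ablation rows) are *not* consistent
with any per-module arithmetic — the deviations range from +60 to a few
thousand parameters. The experiment grid (`ablation_grid()`) therefore
stores both the reported and the derived value with a consistency flag, and
only consistent rows are asserted exactly. The discrepancies are documented,
not reconciled.

## Profiling convention

`profile_model()` counts trainable parameters over all weights, biases and
BN affine terms, and MACs over convolution and linear layers only (batch
norm, activations and pooling are free), with
$\mathrm{GFLOPs} = 2\,\mathrm{MACs}/10^9$ at a 640×640 input. Under this
convention the baseline profiles to 3.29 GFLOPs and the full lightweight
model to 1.34 GFLOPs — a 59.3% reduction. The commonly quoted one-decimal
figures for this architecture family are each exactly 0.1 higher (3.4/1.4);
no principled counting convention we tested (including pooling, BN and
activation elements at various weights, and other input sizes) reproduces
that constant offset, which is consistent with a fixed overhead term in the
profiler those figures came from. The package reports the convention's own
value and does not add a compatibility constant. The reduction *ratio* is
resolution-independent because the trunk is fully convolutional; the test
suite checks this at two input sizes.

## Augmentation suite

Operators are applied with probability 1 once selected, and every stochastic
operator takes an explicit seed (byte-identical outputs under the same seed).
Fixed parameters follow the field-conditions protocol; where a scale or an
auxiliary constant was unspecified, the package fixes it once and logs it in
the operator's metadata:

* brightness/contrast factors uniform in $[0.8, 1.2]$ (±20%);
* hue/saturation shifts of ±15% *of each channel's full scale* (the
  percentage is given without a scale; full-scale is the interpretation
  used);
* rotation uniform in ±45°, translation ±10% of the side, scaling factor in
  $[0.9, 1.1]$, random crop of 80–100% of the area — all unspecified and
  fixed here;
* rain: drizzle streaks of length 6 px, width 1 px, blur level 1
  (implemented as one 3×3 box-blur pass — the level's units are not
  defined, so the minimal one-step blur is used), brightness ×0.7, streak
  density 5×10⁻⁴ per pixel (unspecified; logged);
* shadow: one 6-vertex polygon spanning the whole image, interior ×0.5
  (darkening factor unspecified; logged);
* fog: alpha blend toward white with coefficient 0.05;
* mud: binomial spot count at density 10⁻⁴ per pixel (≈26 spots on a 512²
  image), radii uniform in $[5, 10]$ px.

`balance_dataset()` tops classes up to an exact per-class target by sampling
source images and operators uniformly (the operator mix across families is
unspecified in the protocol; uniform over the registry is the package's
choice), never touches classes at or above the target, never deletes
originals, and is idempotent.

## Synthetic data

`synth_generate()` draws leaf-like images — a textured soil background, an
elliptical green leaf with vein texture, and class-specific lesions (pale
powder patches, grey blotches, linear scars, orange pustules, large dark
regions, or none for the healthy class) plus additive noise. Generation is a
pure function of (spec, seed). The generator gives the six-class folder
structure, colour statistics that a trivial histogram classifier can
separate above chance (asserted by `separability_check()`, the learnability
floor), and enough texture for the CNN to overfit. It does **not** emulate
real disease morphology, illumination physics, camera noise or intra-class
diversity; a green test passing on it demonstrates that the pipeline and
optimiser work, not that any accuracy transfers to real field data. Real
accuracy tables require the external datasets and are out of scope.

## Training and evaluation protocol

The split is nested: 80:20 into a training pool and an independent test set
(stratified per class), then five folds over the pool, each using one fifth
as validation (= 20% of the pool) and the rest as sub-training. Per fold the
best-on-validation weights are kept (ties to the earliest epoch) and all
five are evaluated on the *same* held-out test set; the report carries
mean ± population standard deviation over the five folds and marks the
representative fold (test accuracy closest to the mean, earliest on ties).
A leakage test asserts that no index ever reaches both weight selection and
testing.

Optimisation maps the reference hyperparameters onto Adam: the "momentum"
value 0.937 is beta1, beta2 is 0.999 (unspecified; Adam's default), weight
decay 5×10⁻⁴ applies to convolution/linear weight matrices only, and the
learning rate decays linearly from `lr0 = 0.001` to `lr0 * lrf` over the
epoch budget — the conventional reading of the `lr0`/`lrf` pair. The loss is
cross-entropy (unstated; the standard choice for this task). Batch norm uses
batch statistics in training with running-statistics momentum 0.1 and
eps 10⁻⁵; weights are Kaiming-normal initialised from the build seed, so a
fixed seed makes whole training runs bit-reproducible. `patience = 0`
disables early stopping. Macro averaging aggregates the per-class precision,
recall and F1 (F1 defined as 0 when precision + recall is 0).

The default configuration (512² images, batch 32, 100 epochs) is the
reference protocol; the package's own test suite exercises the identical
code path at its chosen smoke scale — 48² synthetic images, a width-reduced
plan (stem 8, widths 8/16/16/32, single repeats) for the five-fold run, and
a 32²/40-epoch two-class overfit check — sizes picked so the whole protocol
remains a routine desk run while still covering every module, including the
attention downsamplers and the fusion block.

`activation_heatmap()` projects the pre-pooling head activations onto the
class weight vector of the final linear layer, min–max normalises to
$[0, 1]$ (a constant map degenerates to 0.5), bilinearly upsamples to the
input size and blends an overlay. On constant input the interior of the map
is near-constant; only zero-padding at the borders breaks the symmetry,
which the test accounts for by checking the interior.

## ONNX export

`export_onnx()` writes a genuine ONNX protobuf (hand-encoded proto3 wire
format, opset 13, fixed input shape, default `(1, 3, 512, 512)`) of the
eval-mode graph: dropout is removed and batch-norm running statistics ship
as initializers. Weights are stored as DOUBLE tensors — valid ONNX, chosen
so that the conversion is lossless rather than rounded through float32.
Dynamic batching is disabled (deployment uses a fixed shape). The parity
check does not reuse the module tree: `onnx_load()` parses the file back
and `onnx_forward()` executes the deserialised nodes purely from their
attributes and initializer payloads, which makes it a genuine second route
through the serialised graph. Supported operators are exactly the exporter's
emission set (Conv, BatchNormalization, Relu, Sigmoid, Mul, Add, Concat,
Split, MaxPool, AveragePool, global pools, channel reductions, Flatten,
Gemm); plans using the ECA, SimAM-style or GAM attention variants have no
ONNX mapping here and fail with an error naming the module. INT8 engine
building is out of scope; the export is the documented calibration hook.

## Known limitations

* The engine is CPU-only and optimised for clarity over throughput;
  reference-scale training (512², 100 epochs, real datasets) is not its
  intended use.
* Whole-model reference totals that disagree with per-module arithmetic are
  stored but cannot be (and are not) reproduced.
* The reported one-decimal GFLOPs figures differ from the stated counting
  convention by a constant +0.1 (see above); the package reports the
  convention's value.
* The synthetic generator is a pipeline fixture, not a disease simulator.
* ONNX export covers the baseline and CBAM/SE-attended plans only.
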