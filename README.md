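# leafcga

A self-contained R implementation of a **lightweight convolutional classifier
for plant-disease recognition under field conditions**, aimed at researchers
and engineers who need to reason about — and reproduce, to the parameter —
the architecture arithmetic of edge-deployable CNNs, and at anyone who wants
a fully inspectable training/evaluation pipeline for class-per-directory
image datasets.

The model family combines three blocks on top of a standard
convolution/cross-stage backbone with a classification head:

* **CBAM-ADown** — asymmetric dual-branch downsampling with per-branch
  convolutional block attention. ADown average-pools the input (2×2,
  stride 1), splits it into channel halves, sends one half through a 3×3
  stride-2 convolution and the other through a 3×3 stride-2 max pool plus a
  1×1 convolution, and concatenates; CBAM gates each branch output with
  channel attention (shared bias-free MLP `c → c/16 → c` over average- and
  max-pooled descriptors) and spatial attention (7×7 convolution over the
  channel mean/max maps). SE, ECA, SimAM-style and GAM variants are included
  for comparison.
* **C3Ghost** — a cross-stage block whose bottlenecks use ghost
  convolutions: half the channels from a dense convolution, half from a
  cheap 5×5 depthwise transform, cutting stage parameters by roughly a third
  model-wide.
* **AFC-SPPF** — a four-branch pooling-fusion block (identity, a cascade of
  three k×k stride-1 max pools, and 3×3 / 5×5 auxiliary pools) concatenated
  to `4c` channels and compressed by a 1×1 convolution plus a 3×3 depthwise
  convolution; exactly `4c² + 13c` parameters.

All convolutions are bias-free with batch normalisation and SiLU. Every
block has a closed-form parameter count (`param_formula()`), every count is
asserted against the built module, and the assembled reference models close
exactly: **916,594** parameters for the lightweight model vs **1,445,974**
for the baseline — a 36.6% reduction, with a 59.3% FLOP reduction under the
package's counting convention (2 × conv/linear MACs at 640×640).

The neural-network engine — convolution/pooling kernels (RcppArmadillo),
batch norm, backpropagation, Adam — is implemented in the package, as are a
field-condition augmentation suite (colour, geometric, and rain / shadow /
fog / mud weather operators with per-class dataset balancing), a
deterministic synthetic leaf-image generator, a nested five-fold
cross-validation harness with per-class precision/recall/F1 and class
activation heatmaps, and ONNX export with a graph-level parity interpreter.

## Worked example

```r
library(leafcga)

# the two reference architectures, profiled at 640x640
model <- build_model(plan_cga(), seed = 42)
model
#> <model: cga> 916,594 trainable parameters
rep  <- profile_model(model)          # per-layer params + MACs
base <- profile_model(plan_baseline())
c(rep$total_params, base$total_params)
#> [1]  916594 1445974
round(c(rep$gflops, base$gflops), 2)
#> [1] 1.34 3.29

# synthetic 6-class leaf data -> nested cross-validation (small demo scale)
dir <- file.path(tempdir(), "demo")
synth_generate(dir, n_per_class = 20, size = 32, seed = 42)
ds <- read_image_folder(dir)
#> <dataset> 120 images, 6 classes (downy_mildew, fresh_leaf, gray_mold,
#>           leaf_scars, rust, sclerotinia_rot), 32x32
plan <- stage_plan(stem_width = 8, widths = c(8, 16, 16, 32),
                   repeats = c(1, 1, 1, 1), downsampler = "adown",
                   attention = "cbam", stage_block = "c3ghost",
                   afc_placement = 4, num_classes = 6)
cv <- cross_validate(plan, ds,
                     train_config(image_size = 32, batch_size = 16,
                                  epochs = 12, seed = 42), k = 3)
cv
#> <cross-validation report> 3 folds | test n = 24
#>   accuracy  0.3611 +/- 0.0708
#>   precision 0.3420 +/- 0.0751
#>   recall    0.3611 +/- 0.0708
#>   f1        0.2952 +/- 0.0774
#>   representative fold: 3 (accuracy 0.3333)
```

The report gives the per-fold test metrics of the five (here three)
best-on-validation weight sets, their mean ± population standard deviation,
and the representative fold (test accuracy closest to the mean). At this
deliberately tiny demo scale the width-reduced model reaches ~2× chance
accuracy after 12 epochs; the point of the demo is the protocol, not the
score. `autoplot()` methods draw the confusion matrix, per-fold metrics,
training curves and activation-heatmap overlays, and

```r
export_onnx(model, "model.onnx")              # (1, 3, 512, 512), opset 13
g <- onnx_load("model.onnx")
x <- array(runif(3 * 512 * 512), c(1, 3, 512, 512))
max(abs(onnx_forward(g, x) - model_forward(model, x)))   # ~1e-10
```

round-trips the model through a genuine ONNX file and an independent graph
interpreter.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/leafcga.R profile --model cga        # prints total 916,594
Rscript inst/cli/leafcga.R synth --out leaves --n 50 --seed 42
Rscript inst/cli/leafcga.R augment --dir leaves --target 80 --seed 42
Rscript inst/cli/leafcga.R train --dir leaves --epochs 5 --imgsz 48
Rscript inst/cli/leafcga.R export --model cga --out model.onnx
```

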