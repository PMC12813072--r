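Package: leafcga
Title: Lightweight Attention-Ghost Convolutional Classifier for Field
    Plant-Disease Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained implementation of a lightweight convolutional
    image classifier for plant-disease recognition under field conditions.
    Provides parameter-exact building blocks (attention-augmented asymmetric
    downsampling, ghost-convolution cross-stage blocks, a four-branch
    multi-scale pooling fusion module), declarative model assembly with a
    per-layer parameter and MAC profiler, a field-condition augmentation
    suite (colour, geometric and weather operators with dataset balancing),
    a deterministic synthetic leaf-image generator, a nested five-fold
    cross-validation training harness with per-class metrics and class
    activation heatmaps, and ONNX export with a graph-level parity checker.
    The neural-network engine (convolution, pooling, batch normalisation,
    backpropagation, Adam) is implemented natively in R and C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
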