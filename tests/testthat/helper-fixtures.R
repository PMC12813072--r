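# shared fixtures, generated once per test session

rand_tensor <- function(dm, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(prod(dm)), dm)
}

# small two-class synthetic dataset (10 images/class at 32x32), cached
fixture_2class_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !base::dir.exists(dir)) {
      dir <<- file.path(tempdir(), "lcga_fix2")
      unlink(dir, recursive = TRUE)
      specs <- synth_class_specs()[c("fresh_leaf", "rust")]
      synth_generate(dir, specs, n_per_class = 10, size = 32, seed = 42)
    }
    dir
  }
})

# a leaf-like test image
fixture_image <- function(size = 48, seed = 7) {
  f <- file.path(tempdir(), sprintf("lcga_img_%d_%d.png", size, seed))
  if (!file.exists(f)) {
    img <- leafcga:::with_seed(seed,
      leafcga:::synth_leaf_image(synth_class_specs()$rust, size))
    write_image(img, f)
  }
  read_image(f)
}

# narrow plan used by the training tests (width-reduced, full module mix)
tiny_plan <- function(num_classes = 2, attention = "cbam") {
  stage_plan(stem_width = 8, widths = c(8, 16, 16, 32), repeats = c(1, 1, 1, 1),
             downsampler = "adown", attention = attention,
             stage_block = "c3ghost", afc_placement = 4,
             num_classes = num_classes, name = "tiny")
}

# pixels-only comparison (augmentation ops tag an "op" attribute)
strip_attrs <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}
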