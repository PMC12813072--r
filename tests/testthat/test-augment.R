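# Augmentation operators: ranges, involutions, weather physics, balancing.

test_that("every operator maps valid RGB to valid RGB and preserves size", {
  img <- fixture_image(48)
  for (nm in names(aug_registry())) {
    out <- aug_registry()[[nm]](img, seed = 11)
    expect_identical(dim(out), dim(img), info = nm)
    expect_true(all(out >= 0 & out <= 1), info = nm)
    expect_true(all(is.finite(out)), info = nm)
  }
})

test_that("stochastic operators are byte-deterministic under a fixed seed", {
  img <- fixture_image(48)
  for (nm in c("brightness_contrast", "hue_saturation", "rotate", "translate",
               "random_crop", "rain", "shadow", "mud")) {
    a <- aug_registry()[[nm]](img, seed = 99)
    b <- aug_registry()[[nm]](img, seed = 99)
    expect_identical(strip_attrs(a), strip_attrs(b), info = nm)
    fa <- tempfile(fileext = ".png"); fb <- tempfile(fileext = ".png")
    write_image(a, fa); write_image(b, fb)
    expect_identical(readBin(fa, raw(), file.size(fa)),
                     readBin(fb, raw(), file.size(fb)), info = nm)
  }
})

test_that("resize contracts: identity at target size, any size in, 512 out", {
  img <- fixture_image(48)
  expect_identical(aug_resize(img, 48, 48), img)
  big <- aug_resize(img, 100, 75)
  expect_identical(dim(big), c(75L, 100L, 3L))
  expect_identical(dim(aug_resize(big, 512, 512)), c(512L, 512L, 3L))
})

test_that("colour augmentation respects its stated bounds", {
  img <- fixture_image(48)
  # all-black fixed point under contrast/brightness scaling
  black <- array(0, c(8, 8, 3))
  out <- aug_color(black, "brightness_contrast", seed = 1)
  # contrast pivots at mid-grey, so black maps to (0.5 - 0.5*ct)*b >= 0; the
  # scaling fixed point is exact for pure brightness
  expect_true(all(out >= 0 & out <= 1))
  expect_true(all(abs(out - out[1, 1, 1]) < 1e-12))   # stays constant
  # brightness-only: mean changes by at most 20% (before clipping)
  for (s in 1:10) {
    b <- leafcga:::with_seed(s, stats::runif(1, 0.8, 1.2))
    out <- clamp_mean <- mean(pmin(pmax(img * b, 0), 1))
    expect_lte(abs(clamp_mean - mean(img)) / mean(img), 0.2 + 1e-9)
  }
  # hue/sat shift keeps the value channel, so pixel-wise max is preserved
  hs <- aug_color(img, "hue_saturation", seed = 5)
  expect_equal(pmax(hs[, , 1], hs[, , 2], hs[, , 3]),
               pmax(img[, , 1], img[, , 2], img[, , 3]), tolerance = 1e-8)
})

test_that("geometric involutions hold exactly", {
  img <- fixture_image(48)
  expect_identical(strip_attrs(aug_geometric(aug_geometric(img, "hflip"), "hflip")), img)
  expect_identical(strip_attrs(aug_geometric(aug_geometric(img, "vflip"), "vflip")), img)
  # vflip preserves the pixel-value histogram exactly
  expect_identical(sort(as.vector(aug_geometric(img, "vflip"))),
                   sort(as.vector(img)))
  # four quarter turns are the identity
  r <- img
  for (i in 1:4) r <- aug_geometric(r, "rotate", angle = 90)
  expect_identical(strip_attrs(r), img)
  # flip_combo is the two flips composed
  expect_identical(strip_attrs(aug_geometric(img, "flip_combo")),
                   strip_attrs(aug_geometric(aug_geometric(img, "hflip"), "vflip")))
})

test_that("rain overlay: streak count, brightness factor and determinism", {
  grey <- array(0.5, c(64, 64, 3))
  out <- weather_rain(grey, seed = 3)
  op <- attr(out, "op")
  expect_identical(op$kind, "weather_rain")
  expect_identical(op$params$drop_length, 6)
  expect_identical(op$params$brightness, 0.7)
  expect_gt(sum(out != 0.5 * 0.7), 0)       # some pixels touched
  # brightness: output mean = 0.7 * (mean of the blurred streak overlay)
  overlaid <- out / 0.7
  expect_equal(mean(out), 0.7 * mean(overlaid), tolerance = 1e-12)
  expect_gt(mean(overlaid), 0.5)            # streaks brighten a mid-grey image
})

test_that("shadow polygon darkens only, with 6 vertices", {
  img <- fixture_image(48)
  out <- weather_shadow(img, seed = 8)
  expect_true(all(out <= img + 1e-12))
  expect_identical(attr(out, "op")$params$n_vertices, 6)
  expect_gt(sum(out < img - 1e-12), 0)      # a region was actually darkened
})

test_that("fog blends toward white: identity at 0, variance shrinks at 0.05", {
  img <- fixture_image(48)
  expect_identical(strip_attrs(weather_fog(img, alpha = 0)), img)
  out <- weather_fog(img)
  expect_identical(attr(out, "op")$params$alpha, 0.05)
  expect_lt(stats::var(as.vector(out)), stats::var(as.vector(img)))
})

test_that("mud-spot density matches 1e-4 within 3 standard errors over 200 seeded runs", {
  img <- array(0.5, c(512, 512, 3))
  counts <- vapply(1:200, function(s) {
    attr(weather_mud(img, seed = s), "op")$params$n_spots
  }, integer(1))
  expected <- 1e-4 * 512 * 512               # 26.2 spots per image
  se <- sqrt(expected / 200)                  # binomial, p small
  expect_lt(abs(mean(counts) - expected), 3 * se)
  radii <- unlist(lapply(1:20, function(s)
    attr(weather_mud(img, seed = s), "op")$params$radii))
  expect_true(all(radii >= 5 & radii <= 10))
  # density 0 is the identity
  expect_identical(strip_attrs(weather_mud(img, seed = 1, density = 0)), img)
})

test_that("dataset balancing reaches the target exactly, only from below, idempotently", {
  dir <- file.path(tempdir(), "lcga_balance")
  unlink(dir, recursive = TRUE)
  specs <- synth_class_specs()[c("fresh_leaf", "rust", "gray_mold")]
  synth_generate(dir, specs, n_per_class = 4, size = 32, seed = 1)
  # push one class above the target: it must be left untouched
  extra_dir <- file.path(dir, "rust")
  for (i in 1:8)
    file.copy(file.path(extra_dir, "img_001.png"),
              file.path(extra_dir, sprintf("copy_%d.png", i)))
  mf <- balance_dataset(dir, target = 10, seed = 7)
  counts <- table(mf$class)
  expect_identical(as.integer(counts[["fresh_leaf"]]), 10L)
  expect_identical(as.integer(counts[["gray_mold"]]), 10L)
  expect_identical(as.integer(counts[["rust"]]), 12L)   # above target: unchanged
  # originals never deleted
  expect_true(all(file.exists(file.path(dir, "fresh_leaf",
                                        sprintf("img_%03d.png", 1:4)))))
  # augmented files name their source and operator
  aug_rows <- mf[!is.na(mf$op), ]
  expect_gt(nrow(aug_rows), 0)
  expect_true(all(grepl("__aug", basename(aug_rows$file))))
  # idempotent second run
  mf2 <- balance_dataset(dir, target = 10, seed = 7)
  expect_identical(nrow(mf2), nrow(mf))
  expect_identical(sort(mf2$file), sort(mf$file))
})
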