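# ---- deterministic synthetic leaf-image generator ----------------------------
#
# Produces class-per-directory folders of leaf-like images so that the whole
# pipeline (augmentation, balancing, training, cross-validation, profiling,
# export) is exercisable without any external download. Lesion families
# loosely mimic common sunflower conditions — pale powder patches (downy
# mildew), grey blotches (grey mould), linear marks (scars), large dark
# regions (sclerotinia rot), small orange pustules (rust) and a healthy
# class — enough visual structure for end-to-end tests, with no claim of
# biological realism. Generation is a pure function of (spec, seed).

#' Default synthetic class specifications
#'
#' Six classes differing in lesion family, lesion geometry and leaf tint.
#'
#' @return named list of class specs (fields: `green` base leaf colour,
#'   `lesion` family, `n_range` lesion count range, `size_range` lesion size
#'   as a fraction of the image side, `noise` additive noise sd).
#' @export
synth_class_specs <- function() {
  list(
    downy_mildew = list(green = c(0.30, 0.48, 0.18), lesion = "powder",
                        n_range = c(2, 5), size_range = c(0.08, 0.18),
                        noise = 0.02),
    fresh_leaf = list(green = c(0.16, 0.46, 0.14), lesion = "none",
                      n_range = c(0, 0), size_range = c(0, 0), noise = 0.02),
    gray_mold = list(green = c(0.26, 0.42, 0.16), lesion = "blotch",
                     n_range = c(1, 3), size_range = c(0.10, 0.25),
                     noise = 0.02),
    leaf_scars = list(green = c(0.22, 0.44, 0.16), lesion = "scars",
                      n_range = c(2, 6), size_range = c(0.15, 0.35),
                      noise = 0.02),
    rust = list(green = c(0.24, 0.46, 0.12), lesion = "pustules",
                n_range = c(15, 40), size_range = c(0.012, 0.03),
                noise = 0.02),
    sclerotinia_rot = list(green = c(0.24, 0.40, 0.16), lesion = "region",
                           n_range = c(1, 2), size_range = c(0.22, 0.38),
                           noise = 0.02)
  )
}

# smooth multiplicative texture field in [1-a, 1+a]
smooth_field <- function(H, W, a = 0.15, grain = 8) {
  g <- matrix(stats::runif(grain * grain), grain, grain)
  up <- EBImage::resize(EBImage::Image(g), w = W, h = H)
  f <- t(EBImage::imageData(up))
  1 + a * (2 * f - 1)
}

synth_leaf_image <- function(spec, size) {
  H <- W <- size
  # soil background
  soil <- c(0.42, 0.30, 0.20)
  tex <- smooth_field(H, W, 0.2)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- soil[ch] * tex
  # leaf ellipse
  cx <- W / 2 + stats::runif(1, -0.06, 0.06) * W
  cy <- H / 2 + stats::runif(1, -0.06, 0.06) * H
  rx <- stats::runif(1, 0.30, 0.42) * W
  ry <- stats::runif(1, 0.30, 0.42) * H
  th <- stats::runif(1, 0, pi)
  px <- matrix(rep(seq_len(W), each = H), H, W) - cx
  py <- matrix(rep(seq_len(H), times = W), H, W) - cy
  u <- px * cos(th) + py * sin(th)
  v <- -px * sin(th) + py * cos(th)
  leaf <- (u / rx)^2 + (v / ry)^2 <= 1
  veins <- 1 + 0.10 * sin(u / max(2, size / 24)) * cos(v / max(2, size / 40))
  ltex <- smooth_field(H, W, 0.12)
  green <- spec$green * stats::runif(3, 0.9, 1.1)
  for (ch in 1:3) {
    layer <- img[, , ch]
    layer[leaf] <- (green[ch] * veins * ltex)[leaf]
    img[, , ch] <- layer
  }
  # lesions
  n <- if (spec$n_range[2] > 0)
    sample(spec$n_range[1]:spec$n_range[2], 1) else 0L
  for (i in seq_len(n)) {
    # place inside the leaf (rejection sampling, fall back to centre)
    ok <- FALSE
    for (try in 1:20) {
      lx <- stats::runif(1, cx - rx, cx + rx)
      ly <- stats::runif(1, cy - ry, cy + ry)
      ui <- (lx - cx) * cos(th) + (ly - cy) * sin(th)
      vi <- -(lx - cx) * sin(th) + (ly - cy) * cos(th)
      if ((ui / rx)^2 + (vi / ry)^2 <= 0.65) { ok <- TRUE; break }
    }
    if (!ok) { lx <- cx; ly <- cy }
    sz <- stats::runif(1, spec$size_range[1], spec$size_range[2]) * size
    img <- draw_lesion(img, spec$lesion, lx, ly, sz, leaf)
  }
  img <- img + array(stats::rnorm(H * W * 3, sd = spec$noise), c(H, W, 3))
  clamp01(img)
}

draw_lesion <- function(img, family, lx, ly, sz, leaf) {
  d <- dim(img)
  px <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2]) - lx
  py <- matrix(rep(seq_len(d[1]), times = d[2]), d[1], d[2]) - ly
  r2 <- px^2 + py^2
  blend <- function(mask, col, alpha) {
    mask <- mask & leaf
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[mask] <- (1 - alpha) * layer[mask] + alpha * col[ch]
      img[, , ch] <<- layer
    }
  }
  switch(family,
    powder = blend(r2 <= sz^2, c(0.85, 0.87, 0.80), 0.55),
    blotch = blend(r2 <= sz^2, c(0.45, 0.40, 0.35), 0.70),
    pustules = blend(r2 <= sz^2, c(0.75, 0.40, 0.08), 0.90),
    region = {
      ang <- atan2(py, px)
      wob <- 1 + 0.25 * sin(3 * ang + lx)
      blend(r2 <= (sz * wob)^2, c(0.20, 0.12, 0.08), 0.80)
    },
    scars = {
      th2 <- stats::runif(1, 0, pi)
      along <- px * cos(th2) + py * sin(th2)
      across <- -px * sin(th2) + py * cos(th2)
      blend(abs(across) <= max(1.5, sz * 0.04) & abs(along) <= sz,
            c(0.30, 0.20, 0.10), 0.85)
    },
    none = NULL)
  img
}

#' Generate a synthetic class-per-directory leaf dataset
#'
#' Writes `n_per_class` PNG images for every class spec into
#' `dir/<class>/img_###.png` plus a `manifest.json`. Regeneration with the
#' same arguments is byte-identical.
#'
#' @param dir output folder (created if needed).
#' @param specs class specifications ([synth_class_specs()] by default).
#' @param n_per_class images per class (>= 1).
#' @param size square image side in pixels.
#' @param seed base seed; per-image seeds are derived deterministically.
#' @return data frame manifest (`file`, `class`), invisibly.
#' @export
synth_generate <- function(dir, specs = synth_class_specs(), n_per_class = 50,
                           size = 64, seed = 42) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ci in seq_along(specs)) {
    cl <- names(specs)[ci]
    cdir <- file.path(dir, cl)
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      iseed <- (seed + 131071 * ci + 524287 * i) %% 2147483647
      img <- with_seed(iseed, synth_leaf_image(specs[[ci]], size))
      f <- file.path(cdir, sprintf("img_%03d.png", i))
      write_image(img, f)
      rows[[length(rows) + 1]] <- data.frame(file = f, class = cl,
                                             stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}

#' Sanity-check class separability of a generated dataset
#'
#' Fits a colour-histogram nearest-centroid classifier on the odd-indexed
#' images of every class and reports accuracy on the even-indexed images —
#' a floor guarantee that the fixture is learnable at all, independent of
#' any neural network.
#'
#' @param dir class-per-directory dataset folder.
#' @return held-out accuracy in `[0, 1]`.
#' @export
separability_check <- function(dir) {
  mf <- folder_manifest(dir)
  if (is.null(mf) || length(unique(mf$class)) < 2)
    stop("separability check needs at least 2 classes")
  feat <- function(f) {
    img <- read_image(f)
    unlist(lapply(1:3, function(ch) {
      v <- img[, , ch]
      c(tabulate(findInterval(v, c(0.25, 0.5, 0.75)) + 1L, 4) / length(v),
        mean(v))
    }))
  }
  X <- t(vapply(mf$file, feat, numeric(15)))
  y <- mf$class
  idx <- stats::ave(seq_along(y), y, FUN = seq_along)
  train <- idx %% 2 == 1
  classes <- sort(unique(y))
  centroids <- t(vapply(classes,
                        function(cl) colMeans(X[train & y == cl, , drop = FALSE]),
                        numeric(ncol(X))))
  d2 <- outer(seq_len(sum(!train)), seq_along(classes), Vectorize(function(i, k) {
    sum((X[!train, , drop = FALSE][i, ] - centroids[k, ])^2)
  }))
  pred <- classes[max.col(-d2, ties.method = "first")]
  mean(pred == y[!train])
}
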