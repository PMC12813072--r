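# ---- field-condition augmentation suite --------------------------------------
#
# Three operator families emulate field imaging conditions: colour jitter
# (lighting), geometric transforms (viewpoint) and weather overlays (rain,
# shadow, fog, mud). Stochastic operators take an explicit seed and are fully
# deterministic under it; every operator is applied with probability 1 once
# selected. Each operator records its kind and realised parameters in the
# "op" attribute of the returned image.

tag_op <- function(img, kind, params) {
  attr(img, "op") <- list(kind = kind, params = params)
  img
}

#' Resize an image to a fixed square size
#'
#' Bilinear interpolation; an image already at the target size is returned
#' unchanged.
#'
#' @param img an `(H, W, 3)` image in `[0, 1]` (or a file path).
#' @param w,h target width and height in pixels.
#' @return the resized image.
#' @export
aug_resize <- function(img, w = 512, h = 512) {
  img <- as_image(img)
  d <- dim(img)
  if (d[1] == h && d[2] == w) return(img)
  out <- eb_to_img(EBImage::resize(eb_from_img(img), w = w, h = h))
  clamp01(out)
}

#' Colour augmentation
#'
#' `"brightness_contrast"` draws brightness and contrast factors uniformly
#' from `[0.8, 1.2]` (a +/-20% range); `"hue_saturation"` shifts hue and
#' saturation by up to +/-15% of their full scale; `"combo"` applies both.
#'
#' @param img an `(H, W, 3)` image in `[0, 1]`.
#' @param mode one of `"brightness_contrast"`, `"hue_saturation"`, `"combo"`.
#' @param seed RNG seed making the draw deterministic.
#' @return the augmented image, clipped to `[0, 1]`.
#' @export
aug_color <- function(img, mode = c("brightness_contrast", "hue_saturation",
                                    "combo"), seed = NULL) {
  mode <- match.arg(mode)
  img <- as_image(img)
  with_seed(seed, {
    if (mode %in% c("brightness_contrast", "combo")) {
      b <- stats::runif(1, 0.8, 1.2)
      ct <- stats::runif(1, 0.8, 1.2)
      img <- clamp01(((img - 0.5) * ct + 0.5) * b)
    } else b <- ct <- NA_real_
    if (mode %in% c("hue_saturation", "combo")) {
      dh <- stats::runif(1, -0.15, 0.15)
      dsat <- stats::runif(1, -0.15, 0.15)
      img <- shift_hsv(img, dh, dsat)
    } else dh <- dsat <- NA_real_
    tag_op(img, paste0("color_", mode),
           list(brightness = b, contrast = ct, hue = dh, saturation = dsat))
  })
}

# vectorised RGB <-> HSV (h, s, v all in [0, 1])
shift_hsv <- function(img, dh, ds) {
  d <- dim(img)
  m <- matrix(img, ncol = 3)
  hsv <- t(grDevices::rgb2hsv(t(m), maxColorValue = 1))
  h <- (hsv[, 1] + dh) %% 1
  s <- clamp01(hsv[, 2] + ds)
  v <- hsv[, 3]
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); tt <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, tt, v)))))
  g <- ifelse(i == 0, tt, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, tt,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), d)
}

#' Geometric augmentation
#'
#' Viewpoint transforms: horizontal/vertical flips, their combination,
#' rotation (uniform in +/-45 degrees, or a fixed `angle`; multiples of 90
#' degrees are exact array permutations), translation (+/-10% of the side),
#' scaling (factor in `[0.9, 1.1]`) and random cropping (80-100% of the
#' area, resized back). Output size always equals input size.
#'
#' @param img an `(H, W, 3)` image.
#' @param mode one of `"hflip"`, `"vflip"`, `"flip_combo"`, `"rotate"`,
#'   `"translate"`, `"scale"`, `"random_crop"`.
#' @param seed RNG seed.
#' @param angle fixed rotation angle in degrees (overrides the random draw).
#' @return the transformed image.
#' @export
aug_geometric <- function(img, mode = c("hflip", "vflip", "flip_combo",
                                        "rotate", "translate", "scale",
                                        "random_crop"),
                          seed = NULL, angle = NULL) {
  mode <- match.arg(mode)
  img <- as_image(img)
  d <- dim(img)
  H <- d[1]; W <- d[2]
  with_seed(seed, {
    out <- switch(mode,
      hflip = img[, W:1, , drop = FALSE],
      vflip = img[H:1, , , drop = FALSE],
      flip_combo = img[H:1, W:1, , drop = FALSE],
      rotate = {
        a <- angle %||% stats::runif(1, -45, 45)
        rotate_image(img, a)
      },
      translate = {
        dx <- round(stats::runif(1, -0.1, 0.1) * W)
        dy <- round(stats::runif(1, -0.1, 0.1) * H)
        translate_image(img, dx, dy)
      },
      scale = {
        f <- stats::runif(1, 0.9, 1.1)
        scale_image(img, f)
      },
      random_crop = {
        frac <- stats::runif(1, 0.8, 1.0)
        side <- max(2L, round(sqrt(frac) * min(H, W)))
        r0 <- sample.int(H - side + 1L, 1L)
        c0 <- sample.int(W - side + 1L, 1L)
        aug_resize(img[r0:(r0 + side - 1L), c0:(c0 + side - 1L), , drop = FALSE],
                   W, H)
      })
    dim(out) <- d
    tag_op(out, paste0("geom_", mode), list(seed = seed))
  })
}

rotate_image <- function(img, angle) {
  a <- angle %% 360
  if (a %% 90 == 0) {
    k <- (a %/% 90) %% 4
    out <- img
    for (i in seq_len(k)) {   # exact clockwise quarter turns
      dd <- dim(out)
      out <- aperm(out, c(2, 1, 3))[, dd[1]:1, , drop = FALSE]
    }
    return(out)
  }
  d <- dim(img)
  eb <- EBImage::rotate(eb_from_img(img), a, output.dim = c(d[2], d[1]),
                        bg.col = "black")
  clamp01(eb_to_img(eb))
}

translate_image <- function(img, dx, dy) {
  d <- dim(img)
  out <- array(0, d)
  src_r <- seq_len(d[1]) - dy
  src_c <- seq_len(d[2]) - dx
  ok_r <- which(src_r >= 1 & src_r <= d[1])
  ok_c <- which(src_c >= 1 & src_c <= d[2])
  out[ok_r, ok_c, ] <- img[src_r[ok_r], src_c[ok_c], , drop = FALSE]
  out
}

scale_image <- function(img, f) {
  d <- dim(img)
  nh <- max(2L, round(d[1] * f)); nw <- max(2L, round(d[2] * f))
  z <- aug_resize(img, nw, nh)
  out <- array(0, d)
  if (f >= 1) {
    r0 <- (nh - d[1]) %/% 2; c0 <- (nw - d[2]) %/% 2
    out[, , ] <- z[r0 + seq_len(d[1]), c0 + seq_len(d[2]), , drop = FALSE]
  } else {
    r0 <- (d[1] - nh) %/% 2; c0 <- (d[2] - nw) %/% 2
    out[r0 + seq_len(nh), c0 + seq_len(nw), ] <- z
  }
  out
}

# replicate-padded 3x3 box blur
box_blur3 <- function(img) {
  d <- dim(img)
  acc <- array(0, d)
  for (dr in -1:1) for (dc in -1:1) {
    rr <- pmin(pmax(seq_len(d[1]) + dr, 1), d[1])
    cc <- pmin(pmax(seq_len(d[2]) + dc, 1), d[2])
    acc <- acc + img[rr, cc, , drop = FALSE]
  }
  acc / 9
}

#' Rain (drizzle) weather overlay
#'
#' Draws drizzle streaks of length 6 px and width 1 px, applies one 3x3 box
#' blur pass (blur level 1) and multiplies global brightness by 0.7.
#'
#' @param img an `(H, W, 3)` image.
#' @param seed RNG seed.
#' @param density streak density per pixel (count = `density * H * W`).
#' @param brightness post-overlay brightness factor.
#' @return the rain-augmented image; the realised parameters are recorded in
#'   the `"op"` attribute.
#' @export
weather_rain <- function(img, seed = NULL, density = 5e-4, brightness = 0.7) {
  img <- as_image(img)
  d <- dim(img)
  with_seed(seed, {
    n <- max(1L, round(density * d[1] * d[2]))
    r0 <- sample.int(d[1], n, replace = TRUE)
    c0 <- sample.int(d[2], n, replace = TRUE)
    slant <- stats::runif(n, -0.2, 0.2)
    out <- img
    streak_col <- 0.78
    for (i in seq_len(n)) {
      rr <- r0[i] + 0:5                       # length 6 px
      cc <- round(c0[i] + slant[i] * (0:5))   # width 1 px, slight slant
      ok <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
      if (any(ok)) {
        ij <- cbind(rr[ok], cc[ok])
        for (ch in 1:3)
          out[cbind(ij, ch)] <- 0.3 * out[cbind(ij, ch)] + 0.7 * streak_col
      }
    }
    out <- box_blur3(out)                     # blur level 1
    out <- clamp01(out * brightness)
    tag_op(out, "weather_rain",
           list(drop_length = 6, drop_width = 1, blur = 1,
                brightness = brightness, n_drops = n))
  })
}

#' Shadow weather overlay
#'
#' Darkens the interior of a random 6-vertex polygon whose region of
#' interest spans the entire image.
#'
#' @param img an `(H, W, 3)` image.
#' @param seed RNG seed.
#' @param n_vertices polygon dimension (6, per the augmentation protocol).
#' @param darken multiplicative factor applied inside the polygon.
#' @return the shadowed image (every pixel `<=` its original).
#' @export
weather_shadow <- function(img, seed = NULL, n_vertices = 6, darken = 0.5) {
  img <- as_image(img)
  d <- dim(img)
  with_seed(seed, {
    cx <- stats::runif(1, 0, d[2]); cy <- stats::runif(1, 0, d[1])
    ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
    rad <- stats::runif(n_vertices, 0.2, 0.9) * max(d[1], d[2])
    vx <- cx + rad * cos(ang); vy <- cy + rad * sin(ang)
    mask <- polygon_mask(vx, vy, d[1], d[2])
    out <- img
    for (ch in 1:3) out[, , ch] <- img[, , ch] * ifelse(mask, darken, 1)
    tag_op(out, "weather_shadow",
           list(n_vertices = n_vertices, darken = darken))
  })
}

# even-odd point-in-polygon mask over the pixel grid
polygon_mask <- function(vx, vy, H, W) {
  px <- matrix(rep(seq_len(W), each = H), H, W)
  py <- matrix(rep(seq_len(H), times = W), H, W)
  inside <- matrix(FALSE, H, W)
  n <- length(vx)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Fog weather overlay
#'
#' Alpha-blends the image toward white with the given transparency
#' coefficient (default 0.05).
#'
#' @param img an `(H, W, 3)` image.
#' @param alpha fog transparency coefficient.
#' @return the fogged image.
#' @export
weather_fog <- function(img, alpha = 0.05) {
  img <- as_image(img)
  tag_op(clamp01((1 - alpha) * img + alpha), "weather_fog", list(alpha = alpha))
}

#' Mud-splash weather overlay
#'
#' Draws dark circular mud spots; the spot count is binomial with per-pixel
#' density 1e-4 (about one spot per 10,000 pixels) and radii are uniform in
#' `[5, 10]` pixels. Density 0 returns the image unchanged.
#'
#' @param img an `(H, W, 3)` image.
#' @param seed RNG seed.
#' @param density expected spots per pixel.
#' @return the mud-splashed image; spot count and radii are recorded in the
#'   `"op"` attribute.
#' @export
weather_mud <- function(img, seed = NULL, density = 1e-4) {
  img <- as_image(img)
  d <- dim(img)
  with_seed(seed, {
    n <- stats::rbinom(1, d[1] * d[2], density)
    if (n == 0)
      return(tag_op(img, "weather_mud",
                    list(density = density, n_spots = 0L, radii = numeric(0))))
    r0 <- sample.int(d[1], n, replace = TRUE)
    c0 <- sample.int(d[2], n, replace = TRUE)
    radii <- stats::runif(n, 5, 10)
    out <- img
    mud <- c(0.24, 0.16, 0.08)
    for (i in seq_len(n)) {
      rad <- radii[i]
      rr <- max(1, floor(r0[i] - rad)):min(d[1], ceiling(r0[i] + rad))
      cc <- max(1, floor(c0[i] - rad)):min(d[2], ceiling(c0[i] + rad))
      dist2 <- outer((rr - r0[i])^2, (cc - c0[i])^2, "+")
      hit <- dist2 <= rad^2
      shade <- stats::runif(1, 0.8, 1.2)
      for (ch in 1:3) {
        patch <- out[rr, cc, ch]
        patch[hit] <- 0.15 * patch[hit] + 0.85 * min(1, mud[ch] * shade)
        out[rr, cc, ch] <- patch
      }
    }
    tag_op(out, "weather_mud",
           list(density = density, n_spots = as.integer(n), radii = radii))
  })
}

#' The augmentation operator registry
#'
#' Named list of all fourteen operators, each a `function(img, seed)`.
#' [balance_dataset()] samples uniformly from this registry.
#'
#' @return named list of augmentation functions.
#' @export
aug_registry <- function() {
  list(
    brightness_contrast = function(img, seed) aug_color(img, "brightness_contrast", seed),
    hue_saturation = function(img, seed) aug_color(img, "hue_saturation", seed),
    color_combo = function(img, seed) aug_color(img, "combo", seed),
    hflip = function(img, seed) aug_geometric(img, "hflip", seed),
    vflip = function(img, seed) aug_geometric(img, "vflip", seed),
    rotate = function(img, seed) aug_geometric(img, "rotate", seed),
    flip_combo = function(img, seed) aug_geometric(img, "flip_combo", seed),
    translate = function(img, seed) aug_geometric(img, "translate", seed),
    scale = function(img, seed) aug_geometric(img, "scale", seed),
    random_crop = function(img, seed) aug_geometric(img, "random_crop", seed),
    rain = function(img, seed) weather_rain(img, seed),
    shadow = function(img, seed) weather_shadow(img, seed),
    fog = function(img, seed) weather_fog(img),
    mud = function(img, seed) weather_mud(img, seed)
  )
}

#' Balance a class-per-directory dataset by augmentation
#'
#' Brings every class whose image count is below `target` up to exactly
#' `target` files by writing augmented copies of randomly chosen source
#' images (operators sampled uniformly from [aug_registry()] with derived
#' seeds). Classes at or above the target are left untouched (the
#' below-target-only rule), originals are never deleted, and re-running with
#' the same plan changes nothing.
#'
#' @param dir dataset folder (one subdirectory of PNGs per class).
#' @param target per-class target count.
#' @param seed base RNG seed; per-image seeds are derived from it.
#' @return data frame manifest of all files (columns `file`, `class`,
#'   `source`, `op`, `seed`; `NA` source/op for originals), invisibly writes
#'   `manifest.json` in `dir`.
#' @export
balance_dataset <- function(dir, target, seed = 42) {
  mf <- folder_manifest(dir)
  if (is.null(mf)) stop("no images found under ", dir)
  classes <- sort(unique(mf$class))
  reg <- aug_registry()
  rows <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    files <- mf$file[mf$class == cl]
    if (!length(files)) stop("class has no images: ", cl)
    originals <- files[!grepl("__aug", basename(files))]
    rows[[cl]] <- data.frame(file = files, class = cl, source = NA_character_,
                             op = NA_character_, seed = NA_integer_,
                             stringsAsFactors = FALSE)
    deficit <- target - length(files)
    if (deficit <= 0) next
    new_rows <- vector("list", deficit)
    for (i in seq_len(deficit)) {
      op_seed <- as.integer((seed + 7919 * i + 104729 * ci) %% 2147483647)
      pick <- with_seed(op_seed, {
        list(src = sample(originals, 1), op = sample(names(reg), 1))
      })
      img <- reg[[pick$op]](read_image(pick$src), op_seed)
      stem <- tools::file_path_sans_ext(basename(pick$src))
      out <- file.path(dir, cl, sprintf("%s__aug%04d_%s.png", stem, i, pick$op))
      write_image(img, out)
      new_rows[[i]] <- data.frame(file = out, class = cl, source = pick$src,
                                  op = pick$op, seed = op_seed,
                                  stringsAsFactors = FALSE)
    }
    rows[[paste0(cl, "_aug")]] <- do.call(rbind, new_rows)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE)
  invisible(manifest)
}
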