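# ---- image representation and I/O --------------------------------------------
#
# Images are numeric arrays of shape (height, width, 3) with values in [0, 1]
# (8-bit RGB divided by 255). PNG is the native on-disk format so that
# regeneration under a fixed seed is byte-identical.

as_image <- function(x) {
  if (is.character(x)) return(read_image(x))
  d <- dim(x)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    stop("expected an (H, W, 3) RGB image array")
  if (anyNA(x)) stop("image contains missing values")
  x
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Read an RGB image
#'
#' Reads a PNG (greyscale and alpha channels are expanded/dropped to RGB);
#' other formats are delegated to EBImage when its readers support them.
#'
#' @param path image file.
#' @return an `(H, W, 3)` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
  d <- dim(img)
  if (is.null(d)) stop("not an image: ", path)
  if (length(d) == 2) img <- array(rep(img, 3), c(d, 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2) img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3))
  img
}

#' Write an RGB image as PNG
#'
#' @param img an `(H, W, 3)` array in `[0, 1]`.
#' @param path output file (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp01(as_image(img)), path)
  invisible(path)
}

eb_from_img <- function(img) {
  EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
}

eb_to_img <- function(eb) {
  aperm(EBImage::imageData(eb), c(2, 1, 3))
}

# list class-per-directory image files
folder_manifest <- function(dir) {
  if (!dir.exists(dir)) stop("dataset folder not found: ", dir)
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stop("no class subdirectories in ", dir)
  rows <- lapply(classes, function(cl) {
    files <- sort(list.files(file.path(dir, cl), pattern = "\\.png$",
                             full.names = TRUE))
    if (!length(files)) return(NULL)
    data.frame(file = files, class = cl, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Load a class-per-directory image folder into memory
#'
#' @param dir folder with one subdirectory of PNG images per class.
#' @param size optional square side; images are bilinearly resized to
#'   `size x size` when given.
#' @return a dataset: `list(x, y, classes, files)` with `x` an
#'   `(N, 3, H, W)` array in `[0, 1]` and `y` integer labels.
#' @export
read_image_folder <- function(dir, size = NULL) {
  mf <- folder_manifest(dir)
  if (is.null(mf)) stop("no PNG images under ", dir)
  classes <- sort(unique(mf$class))
  imgs <- lapply(mf$file, function(f) {
    img <- read_image(f)
    if (!is.null(size)) img <- aug_resize(img, size, size)
    img
  })
  hw <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(i) identical(dim(i), hw), logical(1))))
    stop("images differ in size; pass `size` to resize them")
  x <- array(0, c(length(imgs), 3, hw[1], hw[2]))
  for (i in seq_along(imgs)) x[i, , , ] <- aperm(imgs[[i]], c(3, 1, 2))
  structure(list(x = x, y = match(mf$class, classes), classes = classes,
                 files = mf$file),
            class = "lcga_dataset")
}

#' @export
print.lcga_dataset <- function(x, ...) {
  cat(sprintf("<dataset> %d images, %d classes (%s), %dx%d\n",
              length(x$y), length(x$classes),
              paste(x$classes, collapse = ", "),
              dim(x$x)[3], dim(x$x)[4]))
  invisible(x)
}

# subset a dataset by index
dataset_subset <- function(ds, idx) {
  structure(list(x = ds$x[idx, , , , drop = FALSE], y = ds$y[idx],
                 classes = ds$classes, files = ds$files[idx]),
            class = "lcga_dataset")
}
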