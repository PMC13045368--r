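## Image I/O and range conversions. Images move through the package as
## numeric arrays: H x W x 3 in [0, 1] ("unit range") at the boundary,
## and in [-1, 1] ("model range") inside the diffusion model.

#' Convert a unit-range image to model range \[-1, 1\]
#' @param img array in \[0, 1\].
#' @export
unit_to_model <- function(img) img * 2 - 1

#' Convert a model-range image back to unit range, clipping to \[0, 1\]
#' @param img array in \[-1, 1\].
#' @export
model_to_unit <- function(img) pmin(pmax((img + 1) / 2, 0), 1)

ensure_rgb <- function(img) {
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an RGB image", call. = FALSE)
  img
}

#' Read an image patch (PNG or TIFF) as a unit-range RGB array
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param resolution optional square size to resize to (nearest-neighbor
#'   via area-average for downscaling).
#' @export
read_image <- function(path, resolution = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image extension: '%s'", ext), call. = FALSE))
  img <- ensure_rgb(img)
  if (!is.null(resolution)) img <- resize_image(img, resolution)
  img
}

#' Write a unit-range RGB array to PNG or TIFF
#' @param img array in \[0, 1\].
#' @param path output file path.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop(sprintf("unsupported image extension: '%s'", ext), call. = FALSE))
  invisible(path)
}

#' Resize a square-or-rectangular RGB image to `size x size`
#' @param img unit-range array.
#' @param size target side length.
#' @export
resize_image <- function(img, size) {
  d <- dim(img)
  if (d[1] == size && d[2] == size) return(img)
  out <- EBImage::resize(EBImage::Image(img, colormode = "Color"),
                         w = size, h = size)
  a <- as.array(out)
  dim(a) <- c(size, size, 3L)
  a
}

## ---- feature extractor contract ---------------------------------------

#' Construct a feature extractor
#'
#' A feature extractor is a named transform from a unit-range RGB image
#' to a fixed-length numeric vector; the FID family, retrieval and
#' outlier metrics are all computed on such features. Plug in any
#' transform (e.g. features exported from a pretrained network) via this
#' constructor.
#'
#' @param name identifier string.
#' @param dim output feature length.
#' @param fn function(image) -> numeric vector of length `dim`.
#' @export
feature_extractor <- function(name, dim, fn) {
  stopifnot(is.function(fn))
  structure(list(name = name, dim = as.integer(dim), transform = fn),
            class = "feature_extractor")
}

#' Default deterministic desk feature extractor
#'
#' A fixed-seed random-projection + pooled-statistics pipeline: the image
#' is average-pooled to 16x16, flattened and projected through a frozen
#' Gaussian matrix, and concatenated with global color/texture summary
#' statistics (channel means and s.d.s, hue circular components, edge
#' energy, luminance histogram). It requires no downloaded weights and is
#' deterministic, which is what the relative/ordinal metric behavior in
#' this package needs; absolute FID values are not comparable with
#' Inception-based numbers.
#'
#' @param dim total feature length (default 64).
#' @param pool_size pooled image side (default 16).
#' @export
default_feature_extractor <- function(dim = 64L, pool_size = 16L) {
  n_stats <- 16L
  n_proj <- dim - n_stats
  if (n_proj < 1L) stop("dim too small", call. = FALSE)
  d_in <- pool_size * pool_size * 3L
  Wp <- with_seed(987654321L,
    matrix(stats::rnorm(d_in * n_proj, sd = 1 / sqrt(d_in)), d_in, n_proj))
  fn <- function(img) {
    img <- ensure_rgb(img)
    d <- dim(img)
    small <- if (d[1] != pool_size || d[2] != pool_size)
      resize_image(img, pool_size) else img
    proj <- as.vector(t(Wp) %*% as.vector(small))
    rgb <- matrix(img, ncol = 3L)
    hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 1)
    lum <- pmin(pmax(rowMeans(rgb), 0), 1)
    gx <- small[-1, , , drop = FALSE] - small[-pool_size, , , drop = FALSE]
    gy <- small[, -1, , drop = FALSE] - small[, -pool_size, , drop = FALSE]
    stats_vec <- c(colMeans(rgb), apply(rgb, 2, stats::sd),
                   mean(cos(2 * pi * hsv[1, ])), mean(sin(2 * pi * hsv[1, ])),
                   mean(hsv[2, ]), mean(hsv[3, ]),
                   sqrt(mean(gx^2)), sqrt(mean(gy^2)),
                   as.vector(graphics::hist(lum, breaks = seq(0, 1, length.out = 5),
                                            plot = FALSE)$density) / 4)
    c(proj, stats_vec)
  }
  feature_extractor("random-projection-pooled", dim, fn)
}

#' Extract features from a set of images
#' @param images list of unit-range RGB arrays.
#' @param extractor a [feature_extractor()]; default desk extractor.
#' @return n x dim feature matrix.
#' @export
extract_features <- function(images, extractor = default_feature_extractor()) {
  do.call(rbind, lapply(images, extractor$transform))
}
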