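#' @useDynLib pestscout, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal raster conventions: an RGB image is a numeric (H, W, 3) array with
# values in [0, 1], stored on the 8-bit grid (multiples of 1/255) when produced
# by the generators or read from PNG.

assert_rgb <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L ||
      !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric (H, W, 3) RGB array", arg),
         call. = FALSE)
  }
  if (dim(image)[1] < 1L || dim(image)[2] < 1L) {
    stop(sprintf("`%s` is empty", arg), call. = FALSE)
  }
  invisible(image)
}

# snap to the 8-bit grid so that fixture output is byte-exact
img_quantize8 <- function(image) {
  round(pmin(pmax(image, 0), 1) * 255) / 255
}

# run `expr` under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Read an RGB image from a PNG file
#'
#' @param path path to a PNG file.
#' @return A numeric `(H, W, 3)` array with values in `[0, 1]`. Grayscale and
#'   RGBA inputs are expanded/flattened to plain RGB.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 2L) x <- array(rep(x[, , 1], 3L), c(dim(x)[1:2], 3L))
  x[, , 1:3, drop = FALSE]
}

#' Write an RGB image to a PNG file
#'
#' @param image numeric `(H, W, 3)` array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  assert_rgb(image)
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

# bilinear resize through EBImage (which stores rasters x-major)
resize_rgb <- function(image, height, width) {
  assert_rgb(image)
  if (dim(image)[1] == height && dim(image)[2] == width) return(image)
  out <- EBImage::resize(aperm(image, c(2L, 1L, 3L)), w = width, h = height)
  aperm(out, c(2L, 1L, 3L))
}

# Gaussian blur through EBImage
blur_rgb <- function(image, sigma) {
  if (sigma <= 0) return(image)
  out <- EBImage::gblur(aperm(image, c(2L, 1L, 3L)), sigma = sigma)
  pmin(pmax(aperm(out, c(2L, 1L, 3L)), 0), 1)
}
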