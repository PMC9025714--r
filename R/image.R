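#' Construct an RGB image
#'
#' Images are stored as integer arrays of dimension `height x width x 3`
#' with channel intensities in 0..255. This is the currency every other
#' function in the package consumes and returns.
#'
#' @param x An array of dimension `c(height, width, 3)` (numeric or integer)
#'   with values in \[0, 255\], or a single color (length-3 vector) together
#'   with `height` and `width` to make a uniform image.
#' @param height,width Image dimensions, used only when `x` is a single color.
#' @return An integer array of class `rgb_image`.
#' @examples
#' img <- rgb_image(c(200, 30, 60), height = 8, width = 8)
#' dim(img)
#' @export
rgb_image <- function(x, height = NULL, width = NULL) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3, !is.null(height), !is.null(width))
    x <- array(rep(as.numeric(x), each = height * width),
               dim = c(height, width, 3))
  }
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("an RGB image must be a height x width x 3 array", call. = FALSE)
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("image dimensions must be positive", call. = FALSE)
  storage.mode(x) <- "integer"
  if (anyNA(x) || min(x) < 0L || max(x) > 255L)
    stop("channel intensities must lie in [0, 255]", call. = FALSE)
  structure(x, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d>\n", nrow(x), ncol(x)))
  invisible(x)
}

img_height <- function(img) dim(img)[1]
img_width <- function(img) dim(img)[2]

assert_image <- function(img) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  img
}

#' Read a raster image from PNG or JPEG
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An [rgb_image()]. Grayscale input is expanded to three channels;
#'   an alpha channel is dropped.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 2L) raw <- array(raw, dim = c(dim(raw), 1L))
  if (dim(raw)[3] == 1L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  rgb_image(round(raw * 255))
}

#' Write an image as PNG
#'
#' Extraction output is always written as PNG: JPEG recompression would
#' perturb foreground pixels and break the bit-identity contract of
#' [extract_foreground()].
#'
#' @param img An [rgb_image()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- assert_image(img)
  arr <- array(as.numeric(img) / 255, dim = dim(img))
  png::writePNG(arr, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
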