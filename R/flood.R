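#' Flood-fill parameters
#'
#' Settings for the edge-seeded flood fill that marks background pixels.
#' `max_distance` is the color-distance threshold, in raw intensity units:
#' a pixel joins the background when its distance to an already-marked
#' *neighbor* is strictly below `max_distance` (floating-range semantics).
#'
#' @param max_distance Non-negative color-distance threshold. With
#'   `max_distance = 0` the strict inequality blocks all propagation and
#'   only the border pixels themselves are marked.
#' @param connectivity 4 (edge-adjacent neighbors) or 8 (edges + corners).
#' @param metric `"euclidean"` (root sum of squared channel differences) or
#'   `"chebyshev"` (largest per-channel absolute difference, the per-channel
#'   bound style used by OpenCV's loDiff/upDiff).
#' @param range `"floating"` compares each candidate to the neighbor that
#'   reaches it; `"fixed"` compares it to the border seed pixel its region
#'   grew from. Floating range is the default and the intended semantics.
#' @return A `flood_params` list.
#' @examples
#' flood_params(30)
#' @export
flood_params <- function(max_distance,
                         connectivity = 4L,
                         metric = c("euclidean", "chebyshev"),
                         range = c("floating", "fixed")) {
  metric <- match.arg(metric)
  range <- match.arg(range)
  if (!is.numeric(max_distance) || length(max_distance) != 1L ||
      is.na(max_distance) || max_distance < 0)
    stop("max_distance must be a single non-negative number", call. = FALSE)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  structure(list(max_distance = as.numeric(max_distance),
                 connectivity = connectivity,
                 metric = metric,
                 range = range),
            class = "flood_params")
}

#' Color distance between two pixels
#'
#' @param a,b Length-3 numeric vectors of channel intensities in \[0, 255\].
#' @param metric `"euclidean"` or `"chebyshev"`.
#' @return A non-negative scalar; zero iff `a == b` (both metrics).
#' @examples
#' color_distance(c(80, 80, 80), c(100, 100, 100)) # sqrt(1200)
#' @export
color_distance <- function(a, b, metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  stopifnot(length(a) == 3L, length(b) == 3L,
            all(a >= 0 & a <= 255), all(b >= 0 & b <= 255))
  d <- as.numeric(a) - as.numeric(b)
  switch(metric,
         euclidean = sqrt(sum(d * d)),
         chebyshev = max(abs(d)))
}

#' Compute the background mask by edge-seeded flood fill
#'
#' Marks every border pixel as background, then repeatedly marks any
#' neighbor of a marked pixel whose color distance to that marked pixel is
#' strictly less than `max_distance`, until no pixel can be added. The
#' result is the least fixpoint of that rule and is independent of
#' traversal order; the implementation uses a breadth-first queue seeded
#' with the full border.
#'
#' @param img An [rgb_image()].
#' @param params A [flood_params()] object.
#' @return A logical `height x width` matrix, `TRUE` = background. Every
#'   border pixel is `TRUE` for every image and threshold.
#' @examples
#' img <- rgb_image(c(10, 10, 10), height = 5, width = 5)
#' img[2:4, 2:4, ] <- c(200L, 0L, 0L)[rep(1:3, each = 9)]
#' sum(compute_background_mask(img, flood_params(30))) # the 16 ring pixels
#' @export
compute_background_mask <- function(img, params) {
  img <- assert_image(img)
  stopifnot(inherits(params, "flood_params"))
  flood_mask_cpp(as.integer(img), img_height(img), img_width(img),
                 params$max_distance, params$connectivity,
                 match(params$metric, c("euclidean", "chebyshev")),
                 params$range == "floating")
}

#' Extract the foreground by whitening the background
#'
#' Pixels marked background by [compute_background_mask()] are replaced by
#' `fill_color` (white by default); every other pixel is bit-identical to
#' the input.
#'
#' @inheritParams compute_background_mask
#' @param fill_color Length-3 replacement color, default white.
#' @return An [rgb_image()] of identical dimensions.
#' @export
extract_foreground <- function(img, params, fill_color = c(255, 255, 255)) {
  img <- assert_image(img)
  stopifnot(length(fill_color) == 3L,
            all(fill_color >= 0 & fill_color <= 255))
  mask <- compute_background_mask(img, params)
  out <- unclass(img)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[mask] <- as.integer(fill_color[ch])
    out[, , ch] <- plane
  }
  rgb_image(out)
}
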