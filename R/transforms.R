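#' Right-angle augmentation transforms
#'
#' The augmentation set consists of exactly five variants of each source
#' image: the identity, counter-clockwise rotations by 90, 180 and 270
#' degrees, and a horizontal (left-right) flip. All five are pure pixel
#' permutations: no interpolation, no information loss.
#'
#' @format `transform_kinds` is the character vector of the five variant
#'   names, in canonical order.
#' @export
transform_kinds <- c("identity", "rot90", "rot180", "rot270", "hflip")

#' Filename suffix tags for the five transforms, used by the pipeline.
#' @noRd
transform_tags <- c(identity = "id", rot90 = "r90", rot180 = "r180",
                    rot270 = "r270", hflip = "hf")

assert_transform <- function(t) {
  if (!is.character(t) || length(t) != 1L || !t %in% transform_kinds)
    stop("unknown transform: must be one of ",
         paste(transform_kinds, collapse = ", "), call. = FALSE)
  t
}

#' Apply a right-angle transform to an image
#'
#' Rotations are counter-clockwise. `rot90`/`rot270` swap height and
#' width; the others preserve dimensions.
#'
#' @param t One of `"identity"`, `"rot90"`, `"rot180"`, `"rot270"`,
#'   `"hflip"`.
#' @param img An [rgb_image()].
#' @return The transformed [rgb_image()].
#' @examples
#' img <- rgb_image(array(seq_len(6 * 3) %% 256, dim = c(2, 3, 3)))
#' dim(apply_to_image("rot90", img)) # 3 x 2 x 3
#' @export
apply_to_image <- function(t, img) {
  assert_transform(t)
  img <- assert_image(img)
  a <- unclass(img)
  h <- dim(a)[1]; w <- dim(a)[2]
  out <- switch(t,
    identity = a,
    # CCW 90: point (x, y) -> (y, W - x); as arrays: transpose then
    # reverse rows.
    rot90 = aperm(a, c(2, 1, 3))[w:1, , , drop = FALSE],
    rot180 = a[h:1, w:1, , drop = FALSE],
    rot270 = aperm(a, c(2, 1, 3))[, h:1, , drop = FALSE],
    hflip = a[, w:1, , drop = FALSE]
  )
  rgb_image(out)
}

#' Apply a right-angle transform to bounding boxes
#'
#' Boxes use 0-based half-open pixel coordinates `[x0, x1) x [y0, y1)`
#' on an image of size `width x height`. The CCW 90-degree rotation maps
#' the point (x, y) to (y, W - x), so the box maps to
#' `[y0, y1) x [W - x1, W - x0)`; hflip maps it to
#' `[W - x1, W - x0) x [y0, y1)`. Area is always preserved.
#'
#' @param t Transform kind.
#' @param boxes A data frame as returned by [bounding_boxes()].
#' @param width,height Dimensions of the *source* image, in pixels.
#' @return The transformed boxes, valid within the transformed image
#'   bounds (width/height swapped for `rot90`/`rot270`).
#' @examples
#' b <- bounding_boxes("grade_1", x0 = 10, y0 = 5, x1 = 30, y1 = 25)
#' apply_to_box("hflip", b, width = 100, height = 50)
#' @export
apply_to_box <- function(t, boxes, width, height) {
  assert_transform(t)
  boxes <- validate_boxes(boxes, width, height)
  if (nrow(boxes) == 0L) return(boxes)
  w <- width; h <- height
  out <- boxes
  switch(t,
    identity = NULL,
    rot90 = {
      out$x0 <- boxes$y0; out$x1 <- boxes$y1
      out$y0 <- w - boxes$x1; out$y1 <- w - boxes$x0
    },
    rot180 = {
      out$x0 <- w - boxes$x1; out$x1 <- w - boxes$x0
      out$y0 <- h - boxes$y1; out$y1 <- h - boxes$y0
    },
    rot270 = {
      out$x0 <- h - boxes$y1; out$x1 <- h - boxes$y0
      out$y0 <- boxes$x0; out$y1 <- boxes$x1
    },
    hflip = {
      out$x0 <- w - boxes$x1; out$x1 <- w - boxes$x0
    }
  )
  out
}

#' Dimensions of the image produced by a transform
#' @noRd
transformed_dims <- function(t, width, height) {
  if (t %in% c("rot90", "rot270")) c(width = height, height = width)
  else c(width = width, height = height)
}

#' Produce the five-variant augmentation set
#'
#' Returns the identity plus the four non-trivial variants, each with
#' consistently transformed boxes. Class labels are untouched. Five
#' variants per source is what turns 400 annotated photos into a
#' 2000-image training corpus.
#'
#' @param img An [rgb_image()].
#' @param boxes A [bounding_boxes()] data frame for `img`.
#' @return A named list of five `list(image =, boxes =, tag =)` entries,
#'   in the order of `transform_kinds`.
#' @export
augment_set <- function(img, boxes) {
  img <- assert_image(img)
  w <- img_width(img); h <- img_height(img)
  out <- lapply(transform_kinds, function(t) {
    list(image = apply_to_image(t, img),
         boxes = apply_to_box(t, boxes, w, h),
         tag = unname(transform_tags[t]))
  })
  names(out) <- transform_kinds
  out
}
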