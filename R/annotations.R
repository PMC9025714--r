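#' Bounding boxes in internal coordinates
#'
#' The package's internal box convention is 0-based, half-open pixel
#' intervals: a box `[x0, x1) x [y0, y1)` covers columns `x0 .. x1-1` and
#' rows `y0 .. y1-1`. This differs from the labelimg/Pascal-VOC on-disk
#' dialect (1-based, inclusive), which [parse_voc()] and [write_voc()]
#' translate at the boundary.
#'
#' @param grade Character vector of class labels (quality grades).
#' @param x0,y0,x1,y1 Numeric vectors of box extents, recycled to a
#'   common length.
#' @return A data frame with columns `grade`, `x0`, `y0`, `x1`, `y1`.
#' @export
bounding_boxes <- function(grade = character(), x0 = numeric(),
                           y0 = numeric(), x1 = numeric(), y1 = numeric()) {
  df <- data.frame(grade = as.character(grade), x0 = as.numeric(x0),
                   y0 = as.numeric(y0), x1 = as.numeric(x1),
                   y1 = as.numeric(y1), stringsAsFactors = FALSE)
  if (nrow(df) > 0L && any(df$x0 >= df$x1 | df$y0 >= df$y1))
    stop("degenerate bounding box: need x0 < x1 and y0 < y1", call. = FALSE)
  df
}

validate_boxes <- function(boxes, width = NULL, height = NULL) {
  need <- c("grade", "x0", "y0", "x1", "y1")
  if (!is.data.frame(boxes) || !all(need %in% names(boxes)))
    stop("boxes must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(boxes) == 0L) return(boxes)
  if (any(boxes$x0 >= boxes$x1 | boxes$y0 >= boxes$y1))
    stop("degenerate bounding box: need x0 < x1 and y0 < y1", call. = FALSE)
  if (!is.null(width) &&
      any(boxes$x0 < 0 | boxes$x1 > width | boxes$y0 < 0 | boxes$y1 > height))
    stop("bounding box outside image bounds", call. = FALSE)
  boxes
}

#' Grade name / class index mapping
#'
#' Four quality grades by default. The mapping is bijective: names to
#' 0-based class indices in order.
#'
#' @param names Character vector of grade names.
#' @return A `grade_map` character vector; index of a grade = position - 1.
#' @export
grade_map <- function(names = paste0("grade_", 1:4)) {
  names <- as.character(names)
  if (anyDuplicated(names) || length(names) < 1L)
    stop("grade names must be unique and non-empty", call. = FALSE)
  structure(names, class = "grade_map")
}

grade_index <- function(grades, name) {
  i <- match(name, unclass(grades))
  if (anyNA(i))
    stop("grade(s) not in grade map: ",
         paste(unique(name[is.na(i)]), collapse = ", "), call. = FALSE)
  i - 1L
}

grade_name <- function(grades, index) {
  index <- as.integer(index)
  if (any(index < 0L | index >= length(grades)))
    stop("class index outside grade map", call. = FALSE)
  unclass(grades)[index + 1L]
}

#' Parse a labelimg-style Pascal VOC annotation
#'
#' labelimg writes 1-based inclusive pixel coordinates; these are
#' converted to the internal 0-based half-open convention via
#' `x0 = xmin - 1`, `x1 = xmax` (and likewise for y). Boxes that overflow
#' the stated image size are clipped with a warning.
#'
#' @param path Path to the XML file.
#' @return A list with `filename`, `width`, `height` and `boxes`
#'   (a [bounding_boxes()] data frame; empty if the file has no objects).
#' @export
parse_voc <- function(path) {
  doc <- xml2::read_xml(path)
  size <- xml2::xml_find_first(doc, ".//size")
  if (inherits(size, "xml_missing"))
    stop("VOC annotation lacks a <size> element: ", path, call. = FALSE)
  width <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  height <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  if (is.na(width) || is.na(height) || width < 1 || height < 1)
    stop("VOC <size> must give positive width and height: ", path,
         call. = FALSE)
  filename <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))

  objs <- xml2::xml_find_all(doc, ".//object")
  num <- function(o, tag)
    as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0(".//", tag))))
  grade <- vapply(objs, function(o)
    xml2::xml_text(xml2::xml_find_first(o, "./name")), character(1))
  xmin <- vapply(objs, num, numeric(1), "xmin")
  ymin <- vapply(objs, num, numeric(1), "ymin")
  xmax <- vapply(objs, num, numeric(1), "xmax")
  ymax <- vapply(objs, num, numeric(1), "ymax")
  if (length(objs) > 0L) {
    if (anyNA(c(xmin, ymin, xmax, ymax)))
      stop("VOC object with missing bndbox coordinates: ", path, call. = FALSE)
    if (any(xmin >= xmax) || any(ymin >= ymax))
      stop("VOC box with xmin >= xmax or ymin >= ymax: ", path, call. = FALSE)
  }
  x0 <- xmin - 1; x1 <- xmax; y0 <- ymin - 1; y1 <- ymax
  if (length(objs) > 0L &&
      any(x0 < 0 | y0 < 0 | x1 > width | y1 > height)) {
    warning("clipping out-of-bounds box(es) in ", basename(path),
            call. = FALSE)
    x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
    x1 <- pmin(x1, width); y1 <- pmin(y1, height)
  }
  list(filename = filename, width = width, height = height,
       boxes = bounding_boxes(grade, x0, y0, x1, y1))
}

#' Write a labelimg-style Pascal VOC annotation
#'
#' Inverse of [parse_voc()]: internal half-open boxes become 1-based
#' inclusive coordinates (`xmin = x0 + 1`, `xmax = x1`). Round-tripping
#' through [parse_voc()] reproduces the boxes exactly. Grade names are
#' written verbatim; the grade map only applies at YOLO conversion.
#'
#' @param path Output XML path.
#' @param filename Image file name recorded in the annotation.
#' @param width,height Image dimensions in pixels.
#' @param boxes A [bounding_boxes()] data frame.
#' @return `path`, invisibly.
#' @export
write_voc <- function(path, filename, width, height, boxes) {
  boxes <- validate_boxes(boxes, width, height)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", filename)
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", as.character(as.integer(width)))
  xml2::xml_add_child(sz, "height", as.character(as.integer(height)))
  xml2::xml_add_child(sz, "depth", "3")
  xml2::xml_add_child(doc, "segmented", "0")
  for (i in seq_len(nrow(boxes))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", boxes$grade[i])
    xml2::xml_add_child(ob, "pose", "Unspecified")
    xml2::xml_add_child(ob, "truncated", "0")
    xml2::xml_add_child(ob, "difficult", "0")
    bb <- xml2::xml_add_child(ob, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(as.integer(boxes$x0[i] + 1)))
    xml2::xml_add_child(bb, "ymin", as.character(as.integer(boxes$y0[i] + 1)))
    xml2::xml_add_child(bb, "xmax", as.character(as.integer(boxes$x1[i])))
    xml2::xml_add_child(bb, "ymax", as.character(as.integer(boxes$y1[i])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Convert internal boxes to YOLO labels
#'
#' YOLO labels are `class cx cy w h` with the center and extent
#' normalized by image width/height.
#'
#' @param boxes A [bounding_boxes()] data frame.
#' @param width,height Image dimensions in pixels.
#' @param grades A [grade_map()].
#' @return A data frame with columns `class_index`, `cx`, `cy`, `w`, `h`.
#' @examples
#' b <- bounding_boxes("grade_1", x0 = 10, y0 = 5, x1 = 30, y1 = 25)
#' to_yolo(b, width = 100, height = 50, grades = grade_map())
#' @export
to_yolo <- function(boxes, width, height, grades = grade_map()) {
  boxes <- validate_boxes(boxes, width, height)
  data.frame(
    class_index = if (nrow(boxes)) grade_index(grades, boxes$grade) else integer(),
    cx = (boxes$x0 + boxes$x1) / (2 * width),
    cy = (boxes$y0 + boxes$y1) / (2 * height),
    w = (boxes$x1 - boxes$x0) / width,
    h = (boxes$y1 - boxes$y0) / height
  )
}

#' Convert YOLO labels back to internal boxes
#'
#' Inverse of [to_yolo()] up to the 0.5-pixel rounding implied by
#' 6-decimal serialization; results are clipped to image bounds.
#'
#' @param labels Data frame with `class_index`, `cx`, `cy`, `w`, `h`.
#' @param width,height Image dimensions in pixels.
#' @param grades A [grade_map()].
#' @return A [bounding_boxes()] data frame.
#' @export
from_yolo <- function(labels, width, height, grades = grade_map()) {
  need <- c("class_index", "cx", "cy", "w", "h")
  if (!all(need %in% names(labels)))
    stop("YOLO labels need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(labels) == 0L) return(bounding_boxes())
  if (any(labels$w <= 0 | labels$h <= 0 | labels$w > 1 | labels$h > 1))
    stop("YOLO label with w or h outside (0, 1]", call. = FALSE)
  x0 <- pmax((labels$cx - labels$w / 2) * width, 0)
  x1 <- pmin((labels$cx + labels$w / 2) * width, width)
  y0 <- pmax((labels$cy - labels$h / 2) * height, 0)
  y1 <- pmin((labels$cy + labels$h / 2) * height, height)
  bounding_boxes(grade_name(grades, labels$class_index), x0, y0, x1, y1)
}

#' Read and write YOLO label files
#'
#' One `class cx cy w h` line per object, floats at 6 decimal places;
#' an image with zero objects gets an empty file (YOLO convention).
#'
#' @param path Label file path.
#' @param labels Data frame with `class_index`, `cx`, `cy`, `w`, `h`.
#' @return `write_yolo_file()` returns `path` invisibly;
#'   `read_yolo_file()` returns the labels data frame.
#' @export
write_yolo_file <- function(labels, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", labels$class_index,
                   labels$cx, labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_file
#' @export
read_yolo_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(class_index = integer(), cx = numeric(),
                      cy = numeric(), w = numeric(), h = numeric()))
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) != 5L))
    stop("malformed YOLO line in ", path,
         ": expected 5 whitespace-separated fields", call. = FALSE)
  m <- do.call(rbind, lapply(parts, as.numeric))
  data.frame(class_index = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
             w = m[, 4], h = m[, 5])
}

#' Write a YOLOv5-style dataset descriptor
#'
#' @param path Output YAML path.
#' @param train,val Relative paths to the train and test image
#'   directories.
#' @param grades A [grade_map()].
#' @return `path`, invisibly.
#' @export
write_dataset_yaml <- function(path, train, val, grades = grade_map()) {
  yaml::write_yaml(list(train = train, val = val,
                        nc = length(grades),
                        names = as.list(unclass(grades))), path)
  invisible(path)
}
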