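# Independent oracles and small fixture builders used across the suite.

# Naive flood-fill fixpoint: synchronous full-image sweeps until no pixel
# can be added. Deliberately independent of the package's BFS path.
oracle_flood_mask <- function(img, max_distance, connectivity = 4,
                              metric = "euclidean") {
  h <- dim(img)[1]; w <- dim(img)[2]
  a <- array(as.numeric(img), dim(img))
  mask <- matrix(FALSE, h, w)
  mask[c(1, h), ] <- TRUE
  mask[, c(1, w)] <- TRUE
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  repeat {
    added <- FALSE
    for (y in 1:h) for (x in 1:w) {
      if (mask[y, x]) next
      for (o in offs) {
        ny <- y + o[1]; nx <- x + o[2]
        if (ny < 1 || ny > h || nx < 1 || nx > w || !mask[ny, nx]) next
        dv <- a[y, x, ] - a[ny, nx, ]
        d <- if (metric == "euclidean") sqrt(sum(dv^2)) else max(abs(dv))
        if (d < max_distance) {
          mask[y, x] <- TRUE
          added <- TRUE
          break
        }
      }
    }
    if (!added) break
  }
  mask
}

random_test_image <- function(max_side = 16, n_colors = 4) {
  h <- sample(1:max_side, 1)
  w <- sample(1:max_side, 1)
  palette <- matrix(sample(0:255, n_colors * 3, replace = TRUE),
                    ncol = 3)
  idx <- sample(n_colors, h * w, replace = TRUE)
  rgb_image(array(as.numeric(palette[idx, ]), dim = c(h, w, 3)))
}

# Box-transform oracle: rasterize the box as a 0/255 image, transform the
# raster, and take the tight bounding box of the transformed pixels.
oracle_box_transform <- function(t, box, width, height) {
  img <- rgb_image(c(0, 0, 0), height = height, width = width)
  arr <- unclass(img)
  arr[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1, ] <- 255L
  out <- unclass(apply_to_image(t, rgb_image(arr)))[, , 1]
  rows <- which(rowSums(out) > 0)
  cols <- which(colSums(out) > 0)
  bounding_boxes(box$grade, x0 = min(cols) - 1, y0 = min(rows) - 1,
                 x1 = max(cols), y1 = max(rows))
}

random_box <- function(width, height, grade = "grade_1", min_size = 1) {
  repeat {
    x <- sort(sample(0:width, 2))
    y <- sort(sample(0:height, 2))
    if (x[1] == x[2]) x <- if (x[2] < width) x + c(0, 1) else x - c(1, 0)
    if (y[1] == y[2]) y <- if (y[2] < height) y + c(0, 1) else y - c(1, 0)
    if (diff(x) >= min_size && diff(y) >= min_size) break
  }
  bounding_boxes(grade, x[1], y[1], x[2], y[2])
}

# Definitional AP oracle: numerically integrate the precision envelope
# p_env(r) = max precision at recall >= r over a fine recall grid.
oracle_average_precision <- function(tp, n_gt, grid = 2e4) {
  if (n_gt == 0 || !any(tp)) return(0)
  cum_tp <- cumsum(tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(tp)
  r <- (seq_len(grid) - 0.5) / grid
  p_env <- vapply(r, function(ri) {
    ok <- recall >= ri
    if (!any(ok)) 0 else max(precision[ok])
  }, numeric(1))
  mean(p_env)
}

write_voc_fixture <- function(path, filename, width, height, objects) {
  obj_xml <- vapply(objects, function(o) sprintf(
    "<object><name>%s</name><bndbox><xmin>%d</xmin><ymin>%d</ymin><xmax>%d</xmax><ymax>%d</ymax></bndbox></object>",
    o$name, o$xmin, o$ymin, o$xmax, o$ymax), character(1))
  writeLines(sprintf(
    "<annotation><filename>%s</filename><size><width>%d</width><height>%d</height><depth>3</depth></size>%s</annotation>",
    filename, width, height, paste(obj_xml, collapse = "")), path)
  path
}
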