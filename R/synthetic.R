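#' Grade-dependent appearance palette
#'
#' The four quality grades differ in peel color (bright red fading to
#' dull dark red), and in the number of dark surface defect spots, which
#' stand in for the external quality indicators (freshness, maturity,
#' surface condition) used when grading real fruit.
#' @noRd
grade_palette <- function(grade) {
  stopifnot(grade %in% 1:4)
  list(
    list(color = c(205, 30, 55), spots = 0L),
    list(color = c(170, 45, 50), spots = 1L),
    list(color = c(125, 55, 50), spots = 2L),
    list(color = c(80, 50, 45), spots = 4L)
  )[[grade]]
}

#' Specify one synthetic cherry scene
#'
#' A scene is a roughly elliptical fruit with a short stem, rendered on a
#' smoothly varying, border-connected background. The construction
#' guarantees a minimum color separation between any foreground pixel and
#' any adjacent background pixel (`separation_margin`), while adjacent
#' background pixels differ by far less, so edge-seeded flood fill
#' recovers the exact foreground mask for any threshold between the
#' background step size and the margin.
#'
#' @param grade Quality grade, 1-4. Sets the base peel color and the
#'   defect-spot count.
#' @param width,height Scene size in pixels.
#' @param center Fruit center `c(x, y)` in pixel coordinates.
#' @param axes Ellipse semi-axes `c(a, b)` in pixels.
#' @param angle Ellipse orientation in radians.
#' @param fruit_color Base peel color; default from the grade palette.
#' @param n_spots Defect spot count; default from the grade palette.
#' @param stem_length,stem_width Stem dimensions in pixels.
#' @param bg_color Background base color.
#' @param gradient Peak-to-peak amplitude of a linear background
#'   luminance ramp, in intensity units.
#' @param noise Half-width of uniform per-channel background noise, in
#'   intensity units. Uniform (bounded) noise is used so the adjacent-
#'   background color step stays provably below `separation_margin / 2`.
#' @param separation_margin Guaranteed minimum color distance between
#'   foreground and adjacent background pixels.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(grade, width = 96L, height = 96L,
                       center = c(width / 2, height / 2),
                       axes = c(width / 5, height / 6),
                       angle = 0,
                       fruit_color = NULL, n_spots = NULL,
                       stem_length = height / 8, stem_width = 2,
                       bg_color = c(200, 205, 210),
                       gradient = 20, noise = 2,
                       separation_margin = 100) {
  pal <- grade_palette(grade)
  spec <- list(grade = as.integer(grade), width = as.integer(width),
               height = as.integer(height), center = center, axes = axes,
               angle = angle,
               fruit_color = fruit_color %||% pal$color,
               n_spots = as.integer(n_spots %||% pal$spots),
               stem_length = stem_length, stem_width = stem_width,
               bg_color = bg_color, gradient = gradient, noise = noise,
               separation_margin = separation_margin)
  if (spec$separation_margin <= 0)
    stop("separation_margin must be positive", call. = FALSE)
  # fruit + stem must stay >= 2 px inside the border so the background
  # stays border-connected; extents account for the ellipse orientation
  ca <- abs(cos(spec$angle)); sa <- abs(sin(spec$angle))
  ex <- sqrt((spec$axes[1] * ca)^2 + (spec$axes[2] * sa)^2)
  ey <- sqrt((spec$axes[1] * sa)^2 + (spec$axes[2] * ca)^2)
  reach_x <- max(ex, spec$stem_width / 2)
  stem_top <- spec$center[2] - (spec$axes[2] * ca + spec$axes[1] * sa) -
    spec$stem_length
  if (spec$center[1] - reach_x < 2 || spec$center[1] + reach_x > width - 2 ||
      stem_top < 2 || spec$center[2] + ey > height - 2)
    stop("fruit geometry violates the 2-pixel border margin", call. = FALSE)
  structure(spec, class = "scene_spec")
}

#' Render a synthetic scene with exact ground truth
#'
#' Deterministic given `seed`. Returns the rendered image together with
#' the exact foreground mask, its tight bounding box, and the grade
#' label.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed; all randomness (noise, spot placement) is
#'   drawn from one generator seeded with it.
#' @return A list: `image` ([rgb_image()]), `truth` with `mask` (logical
#'   matrix, `TRUE` = foreground), `box` ([bounding_boxes()], one row)
#'   and `grade` (e.g. `"grade_2"`).
#' @export
generate_scene <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(as.integer(seed), render_scene(spec))
}

render_scene <- function(spec) {
  h <- spec$height; w <- spec$width
  # pixel-center coordinates
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)

  # fruit ellipse
  dx <- xs - spec$center[1]; dy <- ys - spec$center[2]
  ca <- cos(spec$angle); sa <- sin(spec$angle)
  u <- (dx * ca + dy * sa) / spec$axes[1]
  v <- (-dx * sa + dy * ca) / spec$axes[2]
  fruit <- (u * u + v * v) <= 1

  # stem: vertical segment from the ellipse top upwards
  top <- spec$center[2] - spec$axes[2] * abs(ca) - spec$axes[1] * abs(sa)
  stem <- abs(xs - spec$center[1]) <= spec$stem_width / 2 &
    ys >= top - spec$stem_length & ys <= top + 1
  mask <- fruit | stem

  # background: base color + linear ramp + bounded uniform noise
  ramp <- spec$gradient * (xs / w + ys / h) / 2
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- spec$bg_color[ch] - ramp
  if (spec$noise > 0) {
    img <- img + array(runif(h * w * 3, -spec$noise, spec$noise),
                       dim = c(h, w, 3))
  }

  # paint fruit, then stem, then defect spots (kept inside the fruit so
  # the foreground/background frontier color is controlled)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[fruit] <- spec$fruit_color[ch]
    plane[stem] <- c(95, 115, 55)[ch]
    img[, , ch] <- plane
  }
  if (spec$n_spots > 0) {
    for (s in seq_len(spec$n_spots)) {
      t0 <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * 0.6
      scx <- spec$center[1] + rr * spec$axes[1] * cos(t0)
      scy <- spec$center[2] + rr * spec$axes[2] * sin(t0)
      srad <- runif(1, 1.5, max(2, min(spec$axes) / 4))
      spot <- ((xs - scx)^2 + (ys - scy)^2 <= srad^2) & fruit
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[spot] <- c(45, 25, 25)[ch]
        img[, , ch] <- plane
      }
    }
  }

  img <- pmin(pmax(round(img), 0), 255)
  ridx <- which(rowSums(mask) > 0); cidx <- which(colSums(mask) > 0)
  box <- bounding_boxes(paste0("grade_", spec$grade),
                        x0 = min(cidx) - 1, y0 = min(ridx) - 1,
                        x1 = max(cidx), y1 = max(ridx))
  list(image = rgb_image(img),
       truth = list(mask = mask, box = box,
                    grade = paste0("grade_", spec$grade)))
}

#' Randomized scene spec within grade-specific ranges
#' @noRd
random_scene_spec <- function(grade, width = 96L, height = 96L) {
  pal <- grade_palette(grade)
  a <- runif(1, width / 6.5, width / 5)
  b <- runif(1, height / 7, height / 5.5)
  angle <- runif(1, -pi / 8, pi / 8)
  stem_len <- runif(1, height / 12, height / 8)
  ca <- abs(cos(angle)); sa <- abs(sin(angle))
  ex <- sqrt((a * ca)^2 + (b * sa)^2)
  ey <- sqrt((a * sa)^2 + (b * ca)^2)
  top_reach <- b * ca + a * sa + stem_len
  cx <- runif(1, ex + 3, width - ex - 3)
  cy <- runif(1, top_reach + 3, height - ey - 3)
  jitter <- round(runif(3, -12, 12))
  col <- pmin(pmax(pal$color + jitter, 0), 255)
  scene_spec(grade, width, height, center = c(cx, cy), axes = c(a, b),
             angle = angle, fruit_color = col, stem_length = stem_len)
}

#' Generate an annotated synthetic dataset on disk
#'
#' Writes `n_per_grade` scenes per grade as PNG images with paired
#' labelimg-dialect VOC XML annotations, emulating a hand-labelled
#' source corpus (100 per grade gives the canonical 400-image set).
#'
#' @param n_per_grade Scenes per grade (>= 1).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param width,height Scene size in pixels.
#' @param noise Background noise half-width passed to every scene.
#' @return Invisibly, a data frame with `source_id`, `grade`,
#'   `image_path`, `ann_path`.
#' @export
generate_dataset <- function(n_per_grade, out_dir, seed = 1L,
                             width = 96L, height = 96L, noise = 2) {
  stopifnot(n_per_grade >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- withr::with_seed(as.integer(seed), {
    out <- list()
    for (g in 1:4) {
      for (i in seq_len(n_per_grade)) {
        spec <- random_scene_spec(g, width, height)
        spec$noise <- noise
        scene <- render_scene(spec)
        id <- sprintf("g%d_%04d", g, i)
        img_path <- file.path(out_dir, paste0(id, ".png"))
        ann_path <- file.path(out_dir, paste0(id, ".xml"))
        write_image(scene$image, img_path)
        write_voc(ann_path, paste0(id, ".png"), width, height,
                  scene$truth$box)
        out[[id]] <- data.frame(source_id = id,
                                grade = scene$truth$grade,
                                image_path = img_path, ann_path = ann_path,
                                stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  invisible(rows)
}

#' Mock detector with tunable quality
#'
#' Turns ground truth into detections at a controllable fidelity so the
#' evaluation stack can be exercised end to end. At `quality = 1` the
#' ground truth is emitted verbatim with confidence 1 and every metric
#' evaluates to exactly 1. As quality decreases, ground-truth objects
#' are dropped, surviving boxes are jittered, and false positives are
#' injected, so precision, recall and AP all degrade (in expectation)
#' monotonically; at `quality = 0` no true detections remain.
#'
#' @param gts Ground-truth data frame (`image_id`, `grade`, boxes).
#' @param quality Real in \[0, 1\].
#' @param seed Integer seed.
#' @param width,height Image bounds for jitter clipping and FP placement.
#' @param grades A [grade_map()] used when inventing FP classes.
#' @return A [detections()] data frame.
#' @export
mock_detector <- function(gts, quality, seed = 1L,
                          width = 96L, height = 96L,
                          grades = grade_map()) {
  stopifnot(quality >= 0, quality <= 1)
  if (quality == 1) {
    return(detections(gts$image_id, gts$grade, rep(1, nrow(gts)),
                      gts$x0, gts$y0, gts$x1, gts$y1))
  }
  withr::with_seed(as.integer(seed), {
    keep <- runif(nrow(gts)) < quality
    kept <- gts[keep, , drop = FALSE]
    jit <- (1 - quality) * 0.6
    n <- nrow(kept)
    bw <- kept$x1 - kept$x0; bh <- kept$y1 - kept$y0
    x0 <- pmax(0, kept$x0 + runif(n, -jit, jit) * bw)
    x1 <- pmin(width, kept$x1 + runif(n, -jit, jit) * bw)
    y0 <- pmax(0, kept$y0 + runif(n, -jit, jit) * bh)
    y1 <- pmin(height, kept$y1 + runif(n, -jit, jit) * bh)
    bad <- x1 - x0 < 1 | y1 - y0 < 1
    x1[bad] <- pmin(width, x0[bad] + 1); y1[bad] <- pmin(height, y0[bad] + 1)
    tps <- detections(kept$image_id, kept$grade,
                      pmin(1, pmax(0, runif(n, 0.5, 1))),
                      x0, y0, x1, y1)
    # false positives: random boxes on random images at a rate that
    # grows as quality drops
    n_fp <- stats::rbinom(1, nrow(gts), 1 - quality)
    fps <- NULL
    if (n_fp > 0) {
      ids <- sample(unique(gts$image_id), n_fp, replace = TRUE)
      fx0 <- runif(n_fp, 0, width - 8); fy0 <- runif(n_fp, 0, height - 8)
      fw <- runif(n_fp, 4, width / 3); fh <- runif(n_fp, 4, height / 3)
      fps <- detections(ids,
                        sample(unclass(grades), n_fp, replace = TRUE),
                        runif(n_fp, 0, 0.8),
                        fx0, fy0, pmin(width, fx0 + fw),
                        pmin(height, fy0 + fh))
    }
    rbind(tps, fps)
  })
}
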