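#' Intersection over union of axis-aligned boxes
#'
#' Boxes use half-open pixel intervals, so area = (x1-x0)*(y1-y0)
#' exactly. Disjoint boxes score 0; identical boxes score 1.
#'
#' @param a,b Data frames with columns `x0`, `y0`, `x1`, `y1`; rows are
#'   paired (recycled if one has a single row).
#' @return Numeric vector of IoU values in \[0, 1\].
#' @examples
#' a <- bounding_boxes("g", 0, 0, 10, 10)
#' b <- bounding_boxes("g", 5, 5, 15, 15)
#' box_iou(a, b) # 25 / 175 = 1/7
#' @export
box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a$x1, b$x1) - pmax(a$x0, b$x0))
  iy <- pmax(0, pmin(a$y1, b$y1) - pmax(a$y0, b$y0))
  inter <- ix * iy
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) +
    (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Construct a detections data frame
#'
#' @param image_id Character vector of image identifiers.
#' @param grade Class labels.
#' @param confidence Scores in \[0, 1\].
#' @param x0,y0,x1,y1 Box extents (internal half-open convention).
#' @return A data frame with those columns.
#' @export
detections <- function(image_id = character(), grade = character(),
                       confidence = numeric(), x0 = numeric(),
                       y0 = numeric(), x1 = numeric(), y1 = numeric()) {
  if (length(confidence) && any(confidence < 0 | confidence > 1))
    stop("confidence must lie in [0, 1]", call. = FALSE)
  data.frame(image_id = as.character(image_id), grade = as.character(grade),
             confidence = as.numeric(confidence), x0 = as.numeric(x0),
             y0 = as.numeric(y0), x1 = as.numeric(x1), y1 = as.numeric(y1),
             stringsAsFactors = FALSE)
}

#' Greedy confidence-ordered matching of detections to ground truth
#'
#' Detections are processed in descending confidence (ties broken by
#' input order, the de-facto VOC/COCO convention). Each detection matches
#' the highest-IoU not-yet-matched ground truth of the same class in the
#' same image, provided IoU >= `iou_threshold`. Each ground truth can be
#' used once; unmatched detections are false positives.
#'
#' @param dets A [detections()] data frame.
#' @param gts A ground-truth data frame with `image_id`, `grade`, `x0`,
#'   `y0`, `x1`, `y1`.
#' @param iou_threshold Matching threshold in \[0, 1\].
#' @return `dets` sorted by descending confidence with a logical `tp`
#'   column appended.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  ord <- order(-dets$confidence)
  dets <- dets[ord, , drop = FALSE]
  tp <- logical(nrow(dets))
  gt_used <- logical(nrow(gts))
  for (i in seq_len(nrow(dets))) {
    cand <- which(!gt_used &
                    gts$image_id == dets$image_id[i] &
                    gts$grade == dets$grade[i])
    if (length(cand) == 0L) next
    ious <- box_iou(dets[i, , drop = FALSE], gts[cand, , drop = FALSE])
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      tp[i] <- TRUE
      gt_used[cand[best]] <- TRUE
    }
  }
  dets$tp <- tp
  rownames(dets) <- NULL
  dets
}

#' Precision, recall and the precision-recall curve
#'
#' Edge conventions (the corpus can be empty): with no detections,
#' precision is vacuously 1 (no false claims) and recall is 0 unless
#' there was nothing to find (`n_gt == 0`), in which case recall is 1.
#'
#' @param tp Logical vector of per-detection true-positive flags, in
#'   descending-confidence order (as produced by [match_detections()]).
#' @param n_gt Number of ground-truth objects (>= 0).
#' @return A list with `precision`, `recall` and `curve` (a data frame of
#'   cumulative `(recall, precision)` points along the confidence sweep).
#' @export
precision_recall <- function(tp, n_gt) {
  stopifnot(n_gt >= 0)
  n <- length(tp)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  curve <- data.frame(
    recall = if (n_gt > 0) cum_tp / n_gt else rep(1, n),
    precision = if (n > 0) cum_tp / (cum_tp + cum_fp) else numeric()
  )
  total_tp <- if (n > 0) cum_tp[n] else 0L
  list(
    precision = if (n == 0L) 1 else total_tp / n,
    recall = if (n_gt == 0L) 1 else total_tp / n_gt,
    curve = curve,
    n_gt = n_gt
  )
}

#' Average precision from a precision-recall sweep
#'
#' All-point ("continuous") interpolation by default: at each recall
#' level, precision is replaced by the maximum precision achieved at any
#' greater-or-equal recall, and the envelope is integrated over recall.
#' The 101-point scheme used by some detector codebases is available for
#' comparison; the two differ by at most O(0.01) at realistic curve
#' densities.
#'
#' @param tp Logical TP flags in descending-confidence order.
#' @param n_gt Number of ground-truth objects.
#' @param interpolation `"all_point"` or `"101_point"`.
#' @return AP in \[0, 1\]; 0 when there are no true positives or no
#'   ground truth.
#' @examples
#' average_precision(c(TRUE, FALSE, TRUE), n_gt = 3) # 5/9
#' @export
average_precision <- function(tp, n_gt,
                              interpolation = c("all_point", "101_point")) {
  interpolation <- match.arg(interpolation)
  if (n_gt == 0L || length(tp) == 0L || !any(tp)) return(0)
  cum_tp <- cumsum(tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(tp)
  # envelope: max precision at >= each recall
  env <- rev(cummax(rev(precision)))
  if (interpolation == "101_point") {
    r_grid <- seq(0, 1, by = 0.01)
    p_at <- vapply(r_grid, function(r) {
      i <- which(recall >= r)
      if (length(i) == 0L) 0 else env[i[1L]]
    }, numeric(1))
    return(mean(p_at))
  }
  prev_r <- c(0, recall[-length(recall)])
  sum((recall - prev_r) * env)
}

#' Evaluate detections against ground truth
#'
#' Produces the standard detector report: per-class and macro-averaged
#' precision, recall, AP at IoU 0.5, and AP averaged over the ten IoU
#' thresholds 0.50, 0.55, ..., 0.95. Classes present in detections but
#' absent from all ground truth contribute false positives to precision
#' but are excluded from the AP macro-average (with a message).
#'
#' @param dets A [detections()] data frame.
#' @param gts Ground-truth data frame (`image_id`, `grade`, boxes).
#' @param iou_threshold Threshold for the headline precision/recall/AP.
#' @param interpolation Passed to [average_precision()].
#' @return A list with `per_class` (data frame) and `overall` (named
#'   numeric: `precision`, `recall`, `ap50`, `ap50_95`).
#' @export
evaluate_detections <- function(dets, gts, iou_threshold = 0.5,
                                interpolation = "all_point") {
  classes <- sort(unique(gts$grade))
  orphan <- setdiff(unique(dets$grade), classes)
  if (length(orphan) > 0L)
    message("classes with detections but no ground truth (pure FP, ",
            "excluded from AP averaging): ", paste(orphan, collapse = ", "))
  thresholds <- seq(0.5, 0.95, by = 0.05)
  per_class <- lapply(classes, function(cl) {
    d <- dets[dets$grade == cl, , drop = FALSE]
    g <- gts[gts$grade == cl, , drop = FALSE]
    m50 <- match_detections(d, g, iou_threshold)
    pr <- precision_recall(m50$tp, nrow(g))
    aps <- vapply(thresholds, function(t) {
      m <- match_detections(d, g, t)
      average_precision(m$tp, nrow(g), interpolation)
    }, numeric(1))
    data.frame(grade = cl, n_gt = nrow(g), n_det = nrow(d),
               precision = pr$precision, recall = pr$recall,
               ap50 = aps[1L], ap50_95 = mean(aps))
  })
  per_class <- do.call(rbind, per_class)
  overall <- c(precision = mean(per_class$precision),
               recall = mean(per_class$recall),
               ap50 = mean(per_class$ap50),
               ap50_95 = mean(per_class$ap50_95))
  list(per_class = per_class, overall = overall)
}

#' Read detections from per-image text files
#'
#' Each file holds `class conf cx cy w h` lines in normalized YOLO
#' coordinates; the file stem is the image id.
#'
#' @param dir Directory of `.txt` detection files.
#' @param width,height Image dimensions used to denormalize.
#' @param grades A [grade_map()].
#' @return A [detections()] data frame.
#' @export
read_detections_dir <- function(dir, width, height, grades = grade_map()) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  out <- lapply(files, function(f) {
    lines <- readLines(f)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(NULL)
    parts <- strsplit(trimws(lines), "\\s+")
    if (any(lengths(parts) != 6L))
      stop("malformed detection line in ", f, call. = FALSE)
    m <- do.call(rbind, lapply(parts, as.numeric))
    labels <- data.frame(class_index = as.integer(m[, 1]),
                         cx = m[, 3], cy = m[, 4], w = m[, 5], h = m[, 6])
    b <- from_yolo(labels, width, height, grades)
    detections(image_id = tools::file_path_sans_ext(basename(f)),
               grade = b$grade, confidence = m[, 2],
               x0 = b$x0, y0 = b$y0, x1 = b$x1, y1 = b$y1)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) detections() else out
}
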