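gt_one <- function(id = "im1", grade = "grade_1")
  data.frame(image_id = id, grade = grade, x0 = 10, y0 = 10, x1 = 30,
             y1 = 30, stringsAsFactors = FALSE)

test_that("box_iou matches area arithmetic", {
  a <- bounding_boxes("g", 0, 0, 10, 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, bounding_boxes("g", 20, 20, 30, 30)), 0)
  expect_equal(box_iou(a, bounding_boxes("g", 5, 5, 15, 15)), 1 / 7)
  # raster cross-check of the 1/7 case: count cells on a grid
  grid <- expand.grid(x = 0:14 + 0.5, y = 0:14 + 0.5)
  in_a <- grid$x < 10 & grid$y < 10
  in_b <- grid$x >= 5 & grid$y >= 5
  expect_equal(sum(in_a & in_b) / sum(in_a | in_b), 1 / 7)
})

test_that("matching is greedy by confidence with single-use ground truth", {
  gts <- gt_one()
  perfect <- detections("im1", "grade_1", 1, 10, 10, 30, 30)
  expect_identical(match_detections(perfect, gts)$tp, TRUE)

  two <- detections(c("im1", "im1"), "grade_1", c(0.9, 0.8),
                    c(10, 11), c(10, 11), c(30, 31), c(30, 31))
  m <- match_detections(two, gts, 0.5)
  expect_identical(m$tp, c(TRUE, FALSE))
  # order of input must not matter: higher confidence wins the GT
  m2 <- match_detections(two[2:1, ], gts, 0.5)
  expect_identical(m2$confidence, c(0.9, 0.8))
  expect_identical(m2$tp, c(TRUE, FALSE))

  wrong_class <- detections("im1", "grade_2", 1, 10, 10, 30, 30)
  expect_identical(match_detections(wrong_class, gts)$tp, FALSE)
  other_image <- detections("im9", "grade_1", 1, 10, 10, 30, 30)
  expect_identical(match_detections(other_image, gts)$tp, FALSE)
})

test_that("precision and recall follow the stated conventions", {
  pr <- precision_recall(c(TRUE, TRUE, FALSE), n_gt = 2)
  expect_equal(pr$precision, 2 / 3)
  expect_equal(pr$recall, 1)
  expect_equal(pr$curve$recall, c(0.5, 1, 1))
  expect_equal(pr$curve$precision, c(1, 1, 2 / 3))

  empty <- precision_recall(logical(0), n_gt = 3)
  expect_equal(empty$precision, 1) # vacuous: no false claims
  expect_equal(empty$recall, 0)

  nothing <- precision_recall(logical(0), n_gt = 0)
  expect_equal(nothing$recall, 1)

  allgood <- precision_recall(c(TRUE, TRUE), n_gt = 2)
  expect_equal(allgood$precision, 1)
  expect_equal(allgood$recall, 1)
})

test_that("average precision reproduces hand-computed envelopes", {
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 3), 5 / 9)
  expect_equal(average_precision(rep(TRUE, 4), 4), 1)
  expect_equal(average_precision(c(FALSE, FALSE), 5), 0)
  expect_equal(average_precision(logical(0), 3), 0)
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 0), 0)
})

test_that("average precision agrees with the definitional integral oracle", {
  withr::with_seed(31, {
    for (i in 1:12) {
      n <- sample(1:10, 1)
      tp <- runif(n) < 0.6
      n_gt <- sum(tp) + sample(0:3, 1)
      if (n_gt == 0) n_gt <- 1
      expect_equal(average_precision(tp, n_gt),
                   oracle_average_precision(tp, n_gt), tolerance = 2e-3,
                   label = sprintf("case %d", i))
    }
  })
})

test_that("AP is invariant to monotone confidence rescaling", {
  gts <- rbind(gt_one("a"), gt_one("b"), gt_one("c"))
  dets <- detections(c("a", "b", "x", "c"), "grade_1",
                     c(0.9, 0.7, 0.5, 0.3),
                     c(10, 10, 50, 12), c(10, 10, 50, 12),
                     c(30, 30, 70, 32), c(30, 30, 72, 32))
  ap1 <- average_precision(match_detections(dets, gts, 0.5)$tp, nrow(gts))
  resc <- dets
  resc$confidence <- dets$confidence^3 / 2 # strictly increasing map
  ap2 <- average_precision(match_detections(resc, gts, 0.5)$tp, nrow(gts))
  expect_identical(ap1, ap2)
})

test_that("101-point interpolation is close to all-point on dense curves", {
  withr::with_seed(32, {
    tp <- runif(300) < 0.7
    ap_all <- average_precision(tp, 250)
    ap_101 <- average_precision(tp, 250, interpolation = "101_point")
    expect_lt(abs(ap_all - ap_101), 0.02)
  })
})

test_that("a verbatim ground-truth detector scores 1.0 on every number", {
  gts <- rbind(gt_one("a", "grade_1"), gt_one("b", "grade_2"),
               gt_one("b", "grade_1"))
  dets <- detections(gts$image_id, gts$grade, 1,
                     gts$x0, gts$y0, gts$x1, gts$y1)
  rep <- evaluate_detections(dets, gts)
  expect_equal(unname(rep$overall), rep(1, 4))
  expect_equal(rep$per_class$ap50_95, rep(1, 2))
})

test_that("AP at IoU exactly 0.7 passes thresholds up to 0.70 only", {
  gts <- data.frame(image_id = "a", grade = "grade_1", x0 = 0, y0 = 0,
                    x1 = 10, y1 = 10, stringsAsFactors = FALSE)
  # det box [0,10) x [0,7): IoU = 70/100 = 0.7 exactly
  dets <- detections("a", "grade_1", 1, 0, 0, 10, 7)
  rep <- evaluate_detections(dets, gts)
  expect_equal(unname(rep$overall["ap50"]), 1)
  expect_equal(unname(rep$overall["ap50_95"]), 0.5)
  # AP@t non-increasing in t
  aps <- vapply(seq(0.5, 0.95, 0.05), function(t)
    average_precision(match_detections(dets, gts, t)$tp, 1), numeric(1))
  expect_true(all(diff(aps) <= 0))
})

test_that("empty detection sets evaluate to vacuous precision, zero recall", {
  gts <- gt_one()
  rep <- evaluate_detections(detections(), gts)
  expect_equal(unname(rep$overall),
               c(1, 0, 0, 0))
})

test_that("classes without ground truth are excluded from AP averaging", {
  gts <- gt_one("a", "grade_1")
  dets <- rbind(
    detections("a", "grade_1", 1, 10, 10, 30, 30),
    detections("a", "grade_9", 0.8, 10, 10, 30, 30))
  expect_message(rep <- evaluate_detections(dets, gts), "grade_9")
  expect_equal(nrow(rep$per_class), 1L)
  expect_equal(unname(rep$overall["ap50"]), 1)
})

test_that("detection files read back into a detections frame", {
  dir <- withr::local_tempdir()
  writeLines(c("0 0.90 0.5 0.5 0.2 0.2", "2 0.40 0.25 0.25 0.1 0.1"),
             file.path(dir, "img_a.txt"))
  writeLines(character(0), file.path(dir, "img_b.txt"))
  d <- read_detections_dir(dir, width = 100, height = 100)
  expect_equal(nrow(d), 2L)
  expect_equal(d$image_id, c("img_a", "img_a"))
  expect_equal(d$grade, c("grade_1", "grade_3"))
  expect_equal(d$x0, c(40, 20))
  expect_equal(d$confidence, c(0.9, 0.4))
})
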