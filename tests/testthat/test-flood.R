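test_that("color_distance matches direct arithmetic and is symmetric", {
  expect_identical(color_distance(c(10, 10, 10), c(10, 10, 10)), 0)
  expect_equal(color_distance(c(80, 80, 80), c(100, 100, 100)), sqrt(1200))
  expect_equal(color_distance(c(0, 0, 0), c(255, 255, 255)), 255 * sqrt(3))
  expect_equal(color_distance(c(0, 0, 0), c(255, 255, 255), "chebyshev"), 255)
  a <- c(13, 200, 7); b <- c(99, 1, 250)
  expect_equal(color_distance(a, b), color_distance(b, a))
  expect_error(color_distance(a, b, metric = "manhattan"))
  expect_error(flood_params(5, metric = "manhattan"))
})

test_that("flood_params validates its arguments", {
  expect_error(flood_params(-1), "non-negative")
  expect_error(flood_params(5, connectivity = 6), "4 or 8")
  p <- flood_params(12.5, 8, "chebyshev", "fixed")
  expect_equal(p$max_distance, 12.5)
  expect_equal(p$connectivity, 8L)
})

test_that("uniform image floods completely; ring blocks a distinct block", {
  uni <- rgb_image(c(50, 90, 130), height = 8, width = 8)
  expect_true(all(compute_background_mask(uni, flood_params(1))))

  ring <- rgb_image(c(10, 10, 10), height = 5, width = 5)
  arr <- unclass(ring)
  for (ch in 1:3) arr[2:4, 2:4, ch] <- c(200L, 0L, 0L)[ch]
  ring <- rgb_image(arr)
  m <- compute_background_mask(ring, flood_params(30))
  expect_equal(sum(m), 16)
  expect_false(any(m[2:4, 2:4]))
})

test_that("concentric rings flip between border-only and full flood at the ring distance", {
  img <- rgb_image(c(80, 80, 80), height = 5, width = 5)
  img[2:4, 2:4, ] <- 100L
  img[3, 3, ] <- 120L
  img <- rgb_image(unclass(img))
  # adjacent-ring distance is sqrt(1200) ~ 34.64: chaining through the
  # middle ring requires the threshold to exceed it
  expect_equal(sum(compute_background_mask(img, flood_params(34))), 16)
  expect_equal(sum(compute_background_mask(img, flood_params(35))), 25)
})

test_that("max_distance = 0 marks only the border (strict inequality)", {
  img <- rgb_image(c(77, 77, 77), height = 6, width = 9)
  m <- compute_background_mask(img, flood_params(0))
  border <- matrix(FALSE, 6, 9)
  border[c(1, 6), ] <- TRUE; border[, c(1, 9)] <- TRUE
  expect_identical(m, border)
})

test_that("BFS mask equals the naive full-sweep fixpoint oracle", {
  withr::with_seed(71, {
    for (i in 1:60) {
      img <- random_test_image()
      d <- runif(1, 0, 300)
      conn <- sample(c(4L, 8L), 1)
      got <- compute_background_mask(img, flood_params(d, conn))
      expect_identical(got, oracle_flood_mask(img, d, conn),
                       label = sprintf("case %d (%dx%d, d=%.2f, conn=%d)",
                                       i, nrow(img), ncol(img), d, conn))
    }
  })
})

test_that("chebyshev metric agrees with its oracle", {
  withr::with_seed(72, {
    for (i in 1:20) {
      img <- random_test_image()
      d <- runif(1, 0, 260)
      got <- compute_background_mask(img, flood_params(d, metric = "chebyshev"))
      expect_identical(got, oracle_flood_mask(img, d, metric = "chebyshev"))
    }
  })
})

test_that("mask grows with the threshold and with connectivity", {
  withr::with_seed(73, {
    for (i in 1:25) {
      img <- random_test_image()
      d <- sort(runif(2, 0, 300))
      m1 <- compute_background_mask(img, flood_params(d[1]))
      m2 <- compute_background_mask(img, flood_params(d[2]))
      expect_true(all(m2[m1]), label = "threshold monotonicity")
      m4 <- compute_background_mask(img, flood_params(d[1], 4L))
      m8 <- compute_background_mask(img, flood_params(d[1], 8L))
      expect_true(all(m8[m4]), label = "connectivity containment")
    }
  })
})

test_that("every border pixel is background for any image and threshold", {
  withr::with_seed(74, {
    for (i in 1:20) {
      img <- random_test_image()
      m <- compute_background_mask(img, flood_params(runif(1, 0, 400)))
      h <- nrow(m); w <- ncol(m)
      expect_true(all(m[c(1, h), ]) && all(m[, c(1, w)]))
    }
  })
})

test_that("1xN and Nx1 images are entirely border, hence background", {
  strip <- rgb_image(array(sample(0:255, 1 * 7 * 3, TRUE), c(1, 7, 3)))
  expect_true(all(compute_background_mask(strip, flood_params(0))))
  col <- rgb_image(array(sample(0:255, 5 * 1 * 3, TRUE), c(5, 1, 3)))
  expect_true(all(compute_background_mask(col, flood_params(0))))
})

test_that("extract_foreground whitens exactly the mask and preserves the rest", {
  withr::with_seed(75, {
    img <- random_test_image(max_side = 12)
    p <- flood_params(60)
    mask <- compute_background_mask(img, p)
    out <- extract_foreground(img, p)
    expect_identical(dim(out), dim(img))
    for (ch in 1:3) {
      plane_in <- unclass(img)[, , ch]
      plane_out <- unclass(out)[, , ch]
      expect_true(all(plane_out[mask] == 255L))
      expect_identical(plane_out[!mask], plane_in[!mask])
    }
    # custom fill color
    out2 <- extract_foreground(img, p, fill_color = c(0, 0, 0))
    expect_true(all(unclass(out2)[, , 1][mask] == 0L))
  })
})

test_that("re-extraction can only grow the background", {
  withr::with_seed(76, {
    for (i in 1:15) {
      img <- random_test_image(max_side = 12)
      p <- flood_params(runif(1, 5, 200))
      m1 <- compute_background_mask(img, p)
      m2 <- compute_background_mask(extract_foreground(img, p), p)
      expect_true(all(m2[m1]))
    }
  })
})

test_that("fixed-range variant is contained in unbounded flood and seeds the border", {
  withr::with_seed(77, {
    img <- random_test_image(max_side = 12)
    m <- compute_background_mask(img, flood_params(40, range = "fixed"))
    h <- nrow(m); w <- ncol(m)
    expect_true(all(m[c(1, h), ]) && all(m[, c(1, w)]))
    m_all <- compute_background_mask(img, flood_params(1000))
    expect_true(all(m_all))
  })
})
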