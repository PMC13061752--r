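test_that("binary extraction recovers well-separated disc centers within 1 px", {
  set.seed(51)
  for (rep in 1:8) {
    h <- 96L; w <- 96L; ppm <- 3
    r_mm <- 2; r_px <- r_mm * ppm
    pts <- random_separated_points(sample(3:7, 1), h, w,
                                   min_sep_px = 2 * r_px + 2, margin = r_px + 1)
    ann <- make_ann(pts, h, w, ppm)
    m <- make_binary_mask(ann, r_mm)
    got <- extract_centers_binary(m$raster)
    expect_equal(nrow(got), nrow(pts))
    # match each recovered center to its nearest generator point
    for (i in seq_len(nrow(got))) {
      d <- sqrt((pts$x - got$x[i])^2 + (pts$y - got$y[i])^2)
      expect_lt(min(d), 1)
    }
  }
})

test_that("binary extraction handles hand-computable and empty cases", {
  expect_equal(nrow(extract_centers_binary(matrix(0, 20, 20))), 0L)
  # one 3x3 block at rows 4-6, cols 10-12 (0-based) -> centroid (11, 5)
  m <- matrix(0, 20, 20)
  m[5:7, 11:13] <- 1
  got <- extract_centers_binary(m)
  expect_equal(got, data.frame(x = 11, y = 5))
})

test_that("binary extraction is monotone in its thresholds", {
  set.seed(52)
  pm <- matrix(runif(40 * 40), 40, 40)
  areas <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th) {
    sum(pm >= th)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
  counts <- vapply(c(0L, 2L, 5L, 10L), function(a) {
    nrow(extract_centers_binary(pm, extraction_params(binary_threshold = 0.7,
                                                      min_region_area_px = a)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("extraction is invariant to annotation input order", {
  set.seed(53)
  pts <- random_separated_points(6, 80, 80, min_sep_px = 14, margin = 7)
  ann1 <- make_ann(pts, 80L, 80L, 3)
  ann2 <- make_ann(pts[sample(nrow(pts)), ], 80L, 80L, 3)
  c1 <- extract_centers_binary(make_binary_mask(ann1, 2)$raster)
  c2 <- extract_centers_binary(make_binary_mask(ann2, 2)$raster)
  o1 <- c1[order(c1$x, c1$y), ]; o2 <- c2[order(c2$x, c2$y), ]
  expect_equal(o1$x, o2$x)
  expect_equal(o1$y, o2$y)
})

test_that("gaussian extraction finds one peak per bump and respects C", {
  # single isotropic bump -> its argmax
  g <- function(h, w, cx, cy, s) {
    outer(0:(h - 1), 0:(w - 1), function(y, x) exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)))
  }
  m1 <- g(40, 40, 20, 15, 3)
  got <- extract_centers_gaussian(m1)
  expect_equal(got, data.frame(x = 20, y = 15))

  # two well-separated bumps of unequal height at C = 0.5: the relative
  # cut is per-area, so the weaker bump still yields a center
  m2 <- g(60, 60, 15, 30, 3) + 0.3 * g(60, 60, 45, 30, 3)
  got2 <- extract_centers_gaussian(m2, extraction_params(gaussian_C = 0.5))
  got2 <- got2[order(got2$x), ]
  expect_equal(nrow(got2), 2L)
  expect_equal(got2$x, c(15, 45))
  expect_equal(got2$y, c(30, 30))

  expect_error(extraction_params(gaussian_C = 0), "0,1")
  expect_error(extraction_params(gaussian_C = 1.5), "0,1")
  expect_equal(nrow(extract_centers_gaussian(matrix(0, 10, 10))), 0L)
})

test_that("gaussian extraction round-trips generated density masks", {
  set.seed(54)
  for (rep in 1:8) {
    h <- 96L; w <- 96L; ppm <- 3
    s_mm <- 1; s_px <- s_mm * ppm
    pts <- random_separated_points(sample(3:6, 1), h, w,
                                   min_sep_px = 6 * s_px + 1, margin = 3 * s_px)
    ann <- make_ann(pts, h, w, ppm)
    d <- make_gaussian_mask(ann, s_mm)
    got <- extract_centers_gaussian(d$raster)
    expect_equal(nrow(got), nrow(pts))
    for (i in seq_len(nrow(got))) {
      dd <- sqrt((pts$x - got$x[i])^2 + (pts$y - got$y[i])^2)
      expect_lt(min(dd), 1)
    }
  }
})

test_that("peak ties break to the smallest row, then column", {
  m <- matrix(0, 10, 10)
  m[4:5, 6:7] <- 1 # flat 2x2 plateau
  got <- extract_centers_gaussian(m, extraction_params(gaussian_C = 1))
  expect_equal(got, data.frame(x = 5, y = 3))
})

test_that("box detections convert to centers, from objects and files", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 0.5 0.25 0.3 0.3", f)
  got <- boxes_to_centers(f, image_size = c(200L, 200L))
  expect_equal(got, data.frame(x = 100, y = 50))

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f2)
  expect_equal(nrow(boxes_to_centers(f2, image_size = c(10L, 10L))), 0L)

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.1 0.1", "0 bad line"), f3)
  expect_error(boxes_to_centers(f3, image_size = c(10L, 10L)), "line 2")

  ann <- make_ann(data.frame(x = c(10, 30), y = c(20, 40)))
  bx <- make_box_labels(ann, 2)
  expect_equal(boxes_to_centers(bx), data.frame(x = c(10, 30), y = c(20, 40)))
})

test_that("connected-component labeling joins diagonal neighbours", {
  m <- matrix(0, 5, 5)
  m[1, 1] <- 1; m[2, 2] <- 1; m[3, 3] <- 1 # one diagonal chain
  m[5, 5] <- 1                             # separate speck
  lab <- label_components(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_equal(lab[1, 1], lab[3, 3])
  expect_false(lab[5, 5] == lab[1, 1])
})
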