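test_that("binary disc rasterization equals the per-pixel distance oracle", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(0:6, 1)
    h <- 40L; w <- 32L
    ppm <- runif(1, 2, 6)
    pts <- data.frame(x = runif(n, 0, w - 1), y = runif(n, 0, h - 1))
    ann <- make_ann(pts, h, w, ppm)
    radius <- runif(1, 0.5, 3)
    got <- make_binary_mask(ann, radius)
    expect_identical(got$raster, oracle_disc_mask(ann, radius))
  }
})

test_that("disc mask handles the worked single-point geometry", {
  # point at 10 mm / 10 mm on a 10 px/mm raster, 2 mm radius
  ann <- make_ann(data.frame(x = 100, y = 100), 200L, 200L, 10)
  m <- make_binary_mask(ann, 2)
  expect_equal(sum(m$raster), sum(oracle_disc_mask(ann, 2)))
  # count is the number of integer grid points within radius 20 of (100,100)
  cnt <- 0L
  for (dx in -20:20) for (dy in -20:20) if (dx^2 + dy^2 <= 400) cnt <- cnt + 1L
  expect_equal(sum(m$raster), cnt)
})

test_that("degenerate discs warn and still mark the nearest pixel", {
  ann <- make_ann(data.frame(x = 10.4, y = 20.6), 50L, 50L, ppm = 1)
  expect_warning(m <- make_binary_mask(ann, 0.3), "covers no pixel")
  expect_equal(sum(m$raster), 1)
  # nearest pixel is (x = 10, y = 21) -> matrix[22, 11], column-major id 522
  expect_equal(which(m$raster == 1), 22L + 10L * 50L)
  # zero points -> all-zero mask
  empty <- make_ann(data.frame(x = numeric(0), y = numeric(0)))
  expect_true(all(make_binary_mask(empty, 2)$raster == 0))
})

test_that("gaussian density masks normalize, localize and superpose", {
  ann <- make_ann(data.frame(x = 50.3, y = 40.8), 100L, 100L, 10)
  d <- make_gaussian_mask(ann, sigma_mm = 0.5)
  expect_equal(sum(d$raster), 1, tolerance = 1e-9)
  am <- which(d$raster == max(d$raster), arr.ind = TRUE)
  expect_equal(unname(am[1, "col"]) - 1L, 50L) # nearest pixel to 50.3
  expect_equal(unname(am[1, "row"]) - 1L, 41L) # nearest pixel to 40.8

  # additivity: two coincident points double the unnormalized raster
  ann2 <- make_ann(data.frame(x = c(50.3, 50.3), y = c(40.8, 40.8)), 100L, 100L, 10)
  u1 <- make_gaussian_mask(ann, 0.5, normalize = FALSE)
  u2 <- make_gaussian_mask(ann2, 0.5, normalize = FALSE)
  expect_equal(u2$raster, 2 * u1$raster, tolerance = 1e-12)

  # closed-form ratio: value at distance sigma_px over the peak = e^-0.5
  annc <- make_ann(data.frame(x = 60, y = 60), 121L, 121L, ppm = 20)
  g <- make_gaussian_mask(annc, sigma_mm = 1, normalize = FALSE) # sigma = 20 px
  expect_equal(g$raster[61, 81] / g$raster[61, 61], exp(-0.5), tolerance = 1e-9)
})

test_that("gaussian masks are translation-equivariant for integer shifts", {
  set.seed(22)
  pts <- data.frame(x = runif(4, 20, 40), y = runif(4, 20, 40))
  ann <- make_ann(pts, 100L, 100L, 4)
  shifted <- make_ann(data.frame(x = pts$x + 7, y = pts$y + 5), 100L, 100L, 4)
  a <- make_gaussian_mask(ann, 1, normalize = FALSE)$raster
  b <- make_gaussian_mask(shifted, 1, normalize = FALSE)$raster
  # compare on the interior that both kernels fully cover
  expect_equal(b[(1 + 5):100, (1 + 7):100], a[1:(100 - 5), 1:(100 - 7)],
               tolerance = 1e-12)
})

test_that("zero-point normalized density degrades to a flagged uniform map", {
  empty <- make_ann(data.frame(x = numeric(0), y = numeric(0)), 10L, 20L)
  expect_warning(d <- make_gaussian_mask(empty, 1), "uniform")
  expect_equal(d$raster, matrix(1 / 200, 10, 20))
  expect_equal(sum(d$raster), 1)
})

test_that("box labels are one per point, centered, and clip at borders", {
  pts <- data.frame(x = c(0, 50, 30), y = c(0, 25, 40))
  ann <- make_ann(pts, 100L, 100L, ppm = 10)
  bx <- make_box_labels(ann, side_mm = 6)
  expect_equal(nrow(bx$boxes), 3L)
  expect_equal(bx$boxes$x, pts$x) # centers preserved, in order
  expect_equal(bx$boxes$y, pts$y)
  expect_equal(bx$boxes$side_px[1], 60)
  # corner box is clipped to the frame but keeps its center
  expect_equal(bx$boxes$x0[1], -0.5)
  expect_equal(bx$boxes$y0[1], -0.5)
  expect_equal(bx$boxes$x1[1], 30)
  expect_error(make_box_labels(ann, 0), "> 0")
})

test_that("YOLO export writes hand-checkable normalized lines", {
  # box center (100, 50), side 60 px on a 200 x 200 image
  ann <- make_ann(data.frame(x = 100, y = 50), 200L, 200L, ppm = 10)
  bx <- make_box_labels(ann, side_mm = 6)
  f <- withr::local_tempfile(fileext = ".txt")
  export_yolo_labels(bx, path = f)
  expect_identical(readLines(f), "0 0.500000 0.250000 0.300000 0.300000")

  # empty set -> empty file
  empty <- make_ann(data.frame(x = numeric(0), y = numeric(0)))
  f2 <- withr::local_tempfile(fileext = ".txt")
  export_yolo_labels(make_box_labels(empty, 6), path = f2)
  expect_length(readLines(f2), 0L)

  # round trip through boxes_to_centers reproduces unclipped centers
  set.seed(23)
  pts <- data.frame(x = runif(5, 40, 160), y = runif(5, 40, 160))
  ann3 <- make_ann(pts, 200L, 200L, 10)
  f3 <- withr::local_tempfile(fileext = ".txt")
  export_yolo_labels(make_box_labels(ann3, 6), path = f3)
  back <- boxes_to_centers(f3, image_size = c(200L, 200L))
  expect_equal(back$x, pts$x, tolerance = 2e-3)
  expect_equal(back$y, pts$y, tolerance = 2e-3)
})

test_that("mask PNG files round-trip through their sidecar conventions", {
  set.seed(24)
  ann <- make_ann(data.frame(x = runif(5, 5, 45), y = runif(5, 5, 45)), 50L, 50L, 3)
  bin <- make_binary_mask(ann, 2)
  f <- withr::local_tempfile(fileext = ".png")
  write_mask_png(bin, f)
  back <- read_mask_png(f, ann$scale)
  expect_identical(back$raster, bin$raster)

  den <- make_gaussian_mask(ann, 1)
  f2 <- withr::local_tempfile(fileext = ".png")
  write_mask_png(den, f2)
  expect_true(file.exists(paste0(f2, ".json")))
  back2 <- read_mask_png(f2, ann$scale)
  expect_lt(max(abs(back2$raster - den$raster)), max(den$raster) / 65535 * 1.01)
  expect_equal(back2$sigma_mm, 1)
})
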