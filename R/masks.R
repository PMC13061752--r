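# Training-target generation: point annotations -> disc masks, Gaussian
# density maps, or fixed-size square box labels.

#' Rasterize point annotations as a binary disc mask
#'
#' Each annotated center contributes a filled disc of physical radius
#' `radius_mm`; overlapping discs merge by union. A pixel is foreground
#' iff its center lies within the radius of some point (no area-overlap
#' antialiasing), so the result is exactly reproducible by a per-pixel
#' distance scan.
#'
#' @param annotations A [point_annotation_set()].
#' @param radius_mm Disc radius in millimetres (default 2).
#' @return An object of class `binary_mask`: a list with `raster`
#'   (H x W matrix of 0/1), `radius_mm`, and the annotation scale.
#' @export
make_binary_mask <- function(annotations, radius_mm = 2) {
  stopifnot(inherits(annotations, "point_annotation_set"))
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0) {
    stop("`radius_mm` must be a single number > 0", call. = FALSE)
  }
  h <- annotations$image_size[1L]; w <- annotations$image_size[2L]
  r_px <- mm_to_px(radius_mm, annotations$scale)
  raster <- matrix(0, h, w)
  pts <- annotations$points
  r2 <- r_px^2
  for (i in seq_len(nrow(pts))) {
    x <- pts$x[i]; y <- pts$y[i]
    c0 <- max(1L, floor(x - r_px) + 1L); c1 <- min(w, ceiling(x + r_px) + 1L)
    r0 <- max(1L, floor(y - r_px) + 1L); r1 <- min(h, ceiling(y + r_px) + 1L)
    rows <- r0:r1; cols <- c0:c1
    dy2 <- ((rows - 1) - y)^2
    dx2 <- ((cols - 1) - x)^2
    hit <- outer(dy2, dx2, `+`) <= r2
    if (!any(hit)) {
      warning(sprintf(
        "disc of radius %g mm (%.3g px) covers no pixel for point %d; marking nearest pixel",
        radius_mm, r_px, i))
      raster[round(y) + 1L, round(x) + 1L] <- 1
    } else {
      raster[rows, cols][hit] <- 1
    }
  }
  structure(list(raster = raster, radius_mm = radius_mm,
                 scale = annotations$scale),
            class = "binary_mask")
}

#' Rasterize point annotations as a Gaussian density map
#'
#' Each annotated center contributes an isotropic 2-D Gaussian kernel
#' `exp(-d^2 / (2 sigma^2))` with `sigma = sigma_mm` converted to pixels.
#' With `normalize = TRUE` the summed map is divided by its total so it
#' is a probability distribution over pixels (the form consumed by the
#' Kullback-Leibler training loss). Kernels are evaluated within a
#' +/- 4 sigma window; the truncated tail carries < 1e-4 of the mass.
#'
#' @param annotations A [point_annotation_set()].
#' @param sigma_mm Kernel standard deviation in millimetres (default 1,
#'   placing ~95% of each kernel's mass within a 2 mm radius).
#' @param normalize Normalize the map to sum to 1 (default `TRUE`).
#' @return An object of class `density_mask`: list with `raster`
#'   (H x W non-negative matrix), `sigma_mm`, `normalized`, `scale`.
#' @export
make_gaussian_mask <- function(annotations, sigma_mm = 1, normalize = TRUE) {
  stopifnot(inherits(annotations, "point_annotation_set"))
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || sigma_mm <= 0) {
    stop("`sigma_mm` must be a single number > 0", call. = FALSE)
  }
  h <- annotations$image_size[1L]; w <- annotations$image_size[2L]
  s_px <- mm_to_px(sigma_mm, annotations$scale)
  raster <- matrix(0, h, w)
  pts <- annotations$points
  if (nrow(pts) == 0L && normalize) {
    warning("no annotated points: normalized density map is uniform")
    return(structure(list(raster = matrix(1 / (h * w), h, w),
                          sigma_mm = sigma_mm, normalized = TRUE,
                          scale = annotations$scale),
                     class = "density_mask"))
  }
  win <- 4 * s_px
  for (i in seq_len(nrow(pts))) {
    x <- pts$x[i]; y <- pts$y[i]
    c0 <- max(1L, floor(x - win) + 1L); c1 <- min(w, ceiling(x + win) + 1L)
    r0 <- max(1L, floor(y - win) + 1L); r1 <- min(h, ceiling(y + win) + 1L)
    rows <- r0:r1; cols <- c0:c1
    ky <- exp(-(((rows - 1) - y)^2) / (2 * s_px^2))
    kx <- exp(-(((cols - 1) - x)^2) / (2 * s_px^2))
    raster[rows, cols] <- raster[rows, cols] + outer(ky, kx)
  }
  if (normalize) raster <- raster / sum(raster)
  structure(list(raster = raster, sigma_mm = sigma_mm,
                 normalized = normalize, scale = annotations$scale),
            class = "density_mask")
}

#' Generate fixed-size square box labels around annotated centers
#'
#' One axis-aligned square of side `side_mm` per point, centered on it.
#' Boxes reaching past the image border are clipped (the clipped extent
#' is recorded) but keep their original center, so box centers always
#' equal the annotated points.
#'
#' @param annotations A [point_annotation_set()].
#' @param side_mm Box side length in millimetres (default 6).
#' @return An object of class `box_set`: data frame `boxes` with columns
#'   `x`, `y` (center, px), `side_px`, and the clipped extent
#'   `x0`, `y0`, `x1`, `y1` (px, in image physical bounds), plus
#'   `image_size`, `side_mm`, `scale`.
#' @export
make_box_labels <- function(annotations, side_mm = 6) {
  stopifnot(inherits(annotations, "point_annotation_set"))
  if (!is.numeric(side_mm) || length(side_mm) != 1L || side_mm <= 0) {
    stop("`side_mm` must be a single number > 0", call. = FALSE)
  }
  h <- annotations$image_size[1L]; w <- annotations$image_size[2L]
  side_px <- mm_to_px(side_mm, annotations$scale)
  pts <- annotations$points
  half <- side_px / 2
  # image physical extent: pixel centers are integers, so the raster
  # spans [-0.5, W-0.5] x [-0.5, H-0.5]
  boxes <- data.frame(
    x = pts$x, y = pts$y, side_px = rep(side_px, nrow(pts)),
    x0 = pmax(pts$x - half, -0.5), y0 = pmax(pts$y - half, -0.5),
    x1 = pmin(pts$x + half, w - 0.5), y1 = pmin(pts$y + half, h - 0.5)
  )
  structure(list(boxes = boxes, image_size = annotations$image_size,
                 side_mm = side_mm, scale = annotations$scale),
            class = "box_set")
}

#' Export box labels in YOLO text format
#'
#' Writes one line per box, `0 cx cy w h`, all four values normalized to
#' \[0,1\] by image width/height. Clipped boxes export their clipped
#' extent (center and size of the visible part).
#'
#' @param boxes A [make_box_labels()] result.
#' @param image_size `c(height, width)`; defaults to the set's own.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_yolo_labels <- function(boxes, image_size = boxes$image_size, path) {
  stopifnot(inherits(boxes, "box_set"))
  h <- image_size[1L]; w <- image_size[2L]
  b <- boxes$boxes
  lines <- character(0)
  if (nrow(b) > 0L) {
    cx <- (b$x0 + b$x1) / 2; cy <- (b$y0 + b$y1) / 2
    bw <- b$x1 - b$x0;       bh <- b$y1 - b$y0
    lines <- sprintf("0 %.6f %.6f %.6f %.6f", cx / w, cy / h, bw / w, bh / h)
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop(sprintf("cannot write labels to '%s': %s",
                                path, conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Save a training-target mask as PNG
#'
#' Binary masks are written as 8-bit grayscale with values \{0, 255\}.
#' Density maps are scaled by their maximum and written as 16-bit
#' grayscale, with the maximum stored in a JSON sidecar
#' (`<path>.json`) so the map can be recovered up to 16-bit
#' quantization.
#'
#' @param mask A `binary_mask` or `density_mask`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  if (inherits(mask, "binary_mask")) {
    png::writePNG(mask$raster, path)
  } else if (inherits(mask, "density_mask")) {
    mx <- max(mask$raster)
    scaled <- if (mx > 0) mask$raster / mx else mask$raster
    write_png16(scaled, path)
    jsonlite::write_json(
      list(max = mx, sigma_mm = mask$sigma_mm, normalized = mask$normalized),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    stop("`mask` must be a binary_mask or density_mask", call. = FALSE)
  }
  invisible(path)
}

#' Load a training-target mask saved by [write_mask_png()]
#'
#' @param path PNG path. If a `<path>.json` sidecar exists the file is
#'   read back as a density map (rescaled by the stored maximum),
#'   otherwise as a binary mask.
#' @param scale A [scale_calibration()] to attach.
#' @return A `binary_mask` or `density_mask`.
#' @export
read_mask_png <- function(path, scale) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    structure(list(raster = img * meta$max, sigma_mm = meta$sigma_mm,
                   normalized = isTRUE(meta$normalized), scale = as_scale(scale)),
              class = "density_mask")
  } else {
    structure(list(raster = (img > 0.5) + 0, radius_mm = NA_real_,
                   scale = as_scale(scale)),
              class = "binary_mask")
  }
}
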