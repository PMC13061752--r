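# Point annotations, image geometry and the mm <-> pixel calibration.
#
# Coordinate convention used throughout the package: x indexes columns,
# y indexes rows, the origin is the top-left pixel, coordinates are
# 0-based and pixel centers sit at integer coordinates. An R matrix
# element raster[r, c] therefore has its center at (x = c - 1, y = r - 1).

#' Scale calibration between millimetres and pixels
#'
#' Physical parameters of the method (disc radius, box side, matching
#' radius) are stated in millimetres; rasters are addressed in pixels.
#' A `scale_calibration` carries the pixels-per-millimetre factor that
#' links the two. It is supplied per dataset (or per image, where images
#' were shot at different distances); the package never estimates it
#' from image content.
#'
#' @param px_per_mm Positive finite number of pixels per millimetre.
#' @return An object of class `scale_calibration`.
#' @examples
#' sc <- scale_calibration(10)
#' mm_to_px(2, sc) # 20
#' @export
scale_calibration <- function(px_per_mm) {
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L ||
      !is.finite(px_per_mm) || px_per_mm <= 0) {
    stop("`px_per_mm` must be a single finite number > 0", call. = FALSE)
  }
  structure(list(px_per_mm = as.numeric(px_per_mm)),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("<scale_calibration> %g px/mm\n", x$px_per_mm))
  invisible(x)
}

as_scale <- function(scale) {
  if (inherits(scale, "scale_calibration")) return(scale)
  scale_calibration(scale)
}

#' Convert millimetres to pixels (and back)
#'
#' @param value_mm,value_px Numeric vector of lengths.
#' @param scale A [scale_calibration()] (or a bare px/mm number).
#' @return Numeric vector of converted lengths.
#' @export
mm_to_px <- function(value_mm, scale) {
  scale <- as_scale(scale)
  value_mm * scale$px_per_mm
}

#' @rdname mm_to_px
#' @export
px_to_mm <- function(value_px, scale) {
  scale <- as_scale(scale)
  value_px / scale$px_per_mm
}

#' A set of point annotations for one image
#'
#' Holds the expert-clicked spikelet centers of a single image, in pixel
#' coordinates, together with the image geometry and scale calibration.
#' The number of points is the manual ground-truth count of the image.
#'
#' @param image_id Character scalar identifying the image.
#' @param image_size Integer vector `c(height, width)` in pixels.
#' @param points A data frame with numeric columns `x` and `y` (pixels,
#'   0-based, x = column, y = row); row order is preserved.
#' @param scale A [scale_calibration()].
#' @return An object of class `point_annotation_set`.
#' @export
point_annotation_set <- function(image_id, image_size, points, scale) {
  stopifnot(is.character(image_id), length(image_id) == 1L)
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(is.na(image_size)) || any(image_size < 1L)) {
    stop("`image_size` must be c(height, width) with positive entries", call. = FALSE)
  }
  if (is.matrix(points)) points <- as.data.frame(points)
  if (!is.data.frame(points)) stop("`points` must be a data frame", call. = FALSE)
  if (nrow(points) == 0L && !all(c("x", "y") %in% names(points))) {
    points <- data.frame(x = numeric(0), y = numeric(0))
  }
  if (!all(c("x", "y") %in% names(points))) {
    stop("`points` must have columns `x` and `y`", call. = FALSE)
  }
  points <- data.frame(x = as.numeric(points$x), y = as.numeric(points$y))
  validate_points_in_bounds(points, image_size)
  structure(
    list(image_id = image_id, image_size = image_size,
         points = points, scale = as_scale(scale)),
    class = "point_annotation_set"
  )
}

validate_points_in_bounds <- function(points, image_size) {
  h <- image_size[1L]; w <- image_size[2L]
  bad <- !is.finite(points$x) | !is.finite(points$y) |
    points$x < 0 | points$y < 0 | points$x >= w | points$y >= h
  if (any(bad)) {
    stop(sprintf(
      "point(s) out of bounds for a %dx%d image at row(s): %s",
      h, w, paste(which(bad), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.point_annotation_set <- function(x, ...) {
  cat(sprintf("<point_annotation_set> '%s': %d point(s), image %dx%d px, %g px/mm\n",
              x$image_id, nrow(x$points),
              x$image_size[1L], x$image_size[2L], x$scale$px_per_mm))
  invisible(x)
}

#' Number of annotated points
#'
#' @param annotations A [point_annotation_set()].
#' @return Integer count (the manual ground-truth spikelet count).
#' @export
n_points <- function(annotations) {
  stopifnot(inherits(annotations, "point_annotation_set"))
  nrow(annotations$points)
}

# Sniff the field separator of an annotation table: tab wins if the
# header contains one, else comma. ImageJ emits either depending on the
# export path.
sniff_sep <- function(header_line) {
  if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
}

#' Read point annotations from a CSV/TSV file
#'
#' Accepts the measurement-table dialect of ImageJ point marking: a
#' header row with `X` and `Y` columns (case-insensitive), comma- or
#' tab-separated, any extra columns ignored. Coordinates are pixels.
#'
#' @param path Path to the annotation file.
#' @param image_size `c(height, width)` of the annotated image, pixels.
#' @param scale A [scale_calibration()].
#' @param image_id Image identifier; defaults to the file stem.
#' @return A [point_annotation_set()] with points in file row order.
#' @examples
#' f <- system.file("extdata", "example_annotations.csv", package = "spikeletr")
#' ann <- read_point_annotations(f, image_size = c(400, 250),
#'                               scale = scale_calibration(4))
#' n_points(ann)
#' @export
read_point_annotations <- function(path, image_size, scale,
                                   image_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop(sprintf("annotation file is empty (no header): %s", path), call. = FALSE)
  sep <- sniff_sep(first)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  nm <- toupper(trimws(names(tab)))
  ix <- which(nm == "X"); iy <- which(nm == "Y")
  if (length(ix) != 1L || length(iy) != 1L) {
    stop(sprintf(
      "annotation file must have exactly one X and one Y column (found %d X, %d Y): %s",
      length(ix), length(iy), path
    ), call. = FALSE)
  }
  pts <- data.frame(x = as.numeric(tab[[ix]]), y = as.numeric(tab[[iy]]))
  point_annotation_set(image_id, image_size, pts, scale)
}

#' Write point annotations to a CSV file
#'
#' Writes an `X,Y` header plus one row per point, preserving order and
#' full floating-point precision, so that a read round-trips exactly.
#'
#' @param annotations A [point_annotation_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_point_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "point_annotation_set"))
  lines <- c("X,Y",
             if (nrow(annotations$points) > 0L)
               paste(num_text(annotations$points$x),
                     num_text(annotations$points$y), sep = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop(sprintf("cannot write annotations to '%s': %s",
                                path, conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

# Shortest decimal text that round-trips a double through as.numeric().
num_text <- function(x) {
  vapply(x, function(v) {
    for (d in 1:17) {
      s <- format(v, digits = d, scientific = FALSE, trim = TRUE)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}
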