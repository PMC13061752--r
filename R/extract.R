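# Decoding predicted maps back to point estimates of spikelet centers.

#' Center-extraction parameters
#'
#' @param binary_threshold Probability cut for binarizing a
#'   binary-scheme map, in (0,1); default 0.5.
#' @param min_region_area_px Regions smaller than this many pixels are
#'   discarded; default 0 (keep all).
#' @param gaussian_C Relative peak threshold in (0,1\]: within a
#'   candidate area, pixels below `C` times the area's maximum are
#'   removed before peaks are located; default 0.5.
#' @param gaussian_floor Absolute floor for candidate areas of a
#'   density map, as a fraction of the map's global maximum;
#'   default 1e-4.
#' @return An object of class `extraction_params`.
#' @export
extraction_params <- function(binary_threshold = 0.5,
                              min_region_area_px = 0L,
                              gaussian_C = 0.5,
                              gaussian_floor = 1e-4) {
  if (!(binary_threshold > 0 && binary_threshold < 1)) {
    stop("`binary_threshold` must be in (0,1)", call. = FALSE)
  }
  if (min_region_area_px < 0) stop("`min_region_area_px` must be >= 0", call. = FALSE)
  if (!(gaussian_C > 0 && gaussian_C <= 1)) {
    stop("`gaussian_C` must be in (0,1]", call. = FALSE)
  }
  if (gaussian_floor < 0) stop("`gaussian_floor` must be >= 0", call. = FALSE)
  structure(list(binary_threshold = binary_threshold,
                 min_region_area_px = as.integer(min_region_area_px),
                 gaussian_C = gaussian_C, gaussian_floor = gaussian_floor),
            class = "extraction_params")
}

#' Extract centers from a binary-scheme probability map
#'
#' Binarizes the map at `binary_threshold`, labels foreground regions
#' with 8-connectivity, drops regions smaller than
#' `min_region_area_px`, and returns each surviving region's geometric
#' center (the mean of its member pixel coordinates).
#'
#' @param prob_map H x W matrix of probabilities in \[0,1\].
#' @param params An [extraction_params()].
#' @param scale A [scale_calibration()] (carried along for downstream
#'   physical-unit matching; extraction itself is in pixels).
#' @return Data frame with columns `x`, `y` (0-based pixel coordinates)
#'   — one row per detected center, in region label order.
#' @export
extract_centers_binary <- function(prob_map, params = extraction_params(),
                                   scale = NULL) {
  stopifnot(inherits(params, "extraction_params"))
  lab <- label_components(prob_map >= params$binary_threshold)
  st <- region_stats(lab)
  st <- st[st$area >= max(1L, params$min_region_area_px), , drop = FALSE]
  data.frame(x = st$x, y = st$y)
}

#' Extract centers from a Gaussian-scheme density map
#'
#' Candidate areas are the 8-connected regions above an absolute floor
#' (`gaussian_floor` times the global maximum). Within each area,
#' pixels whose value falls below `gaussian_C` times the area's maximum
#' are removed; the retained pixels are re-labeled, and each resulting
#' region contributes one center: its maximum-value pixel (ties broken
#' toward the smallest row, then column).
#'
#' @param density_map H x W non-negative matrix.
#' @param params An [extraction_params()].
#' @param scale A [scale_calibration()] (see
#'   [extract_centers_binary()]).
#' @return Data frame with columns `x`, `y` (0-based pixel
#'   coordinates).
#' @export
extract_centers_gaussian <- function(density_map, params = extraction_params(),
                                     scale = NULL) {
  stopifnot(inherits(params, "extraction_params"))
  mx <- max(density_map)
  if (mx <= 0) return(data.frame(x = numeric(0), y = numeric(0)))
  floor_abs <- params$gaussian_floor * mx
  cand <- label_components(density_map > floor_abs)
  if (max(cand) == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  keep <- matrix(FALSE, nrow(density_map), ncol(density_map))
  fg <- cand > 0L
  vals <- density_map[fg]; labs <- cand[fg]
  area_max <- as.numeric(tapply(vals, labs, max)) # labels are 1..K
  keep[fg] <- vals >= params$gaussian_C * area_max[labs]
  lab2 <- label_components(keep)
  st <- region_stats(lab2, values = density_map)
  st <- st[st$area >= max(1L, params$min_region_area_px), , drop = FALSE]
  data.frame(x = st$argmax_x, y = st$argmax_y)
}

#' Extract centers from a predicted map (scheme dispatch)
#'
#' @param map H x W matrix as produced by [predict_mask()].
#' @param scheme `"binary"` or `"gaussian"`.
#' @param params An [extraction_params()].
#' @param scale Optional [scale_calibration()].
#' @return Data frame with columns `x`, `y`.
#' @export
extract_centers <- function(map, scheme = c("binary", "gaussian"),
                            params = extraction_params(), scale = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "binary") extract_centers_binary(map, params, scale)
  else extract_centers_gaussian(map, params, scale)
}

#' Centers of box detections
#'
#' Accepts either a [make_box_labels()] result or a YOLO-format label
#' file (`class cx cy w h`, normalized); in the latter case
#' `image_size` denormalizes the coordinates back to pixels. This lets
#' an external box detector's output enter the shared evaluation.
#'
#' @param detections A `box_set` or a path to a YOLO label file.
#' @param image_size `c(height, width)`; required for file input.
#' @return Data frame with columns `x`, `y` (pixel coordinates).
#' @export
boxes_to_centers <- function(detections, image_size = NULL) {
  if (inherits(detections, "box_set")) {
    return(data.frame(x = detections$boxes$x, y = detections$boxes$y))
  }
  if (!is.character(detections) || length(detections) != 1L) {
    stop("`detections` must be a box_set or a file path", call. = FALSE)
  }
  if (is.null(image_size)) {
    stop("`image_size` is required to denormalize a YOLO label file", call. = FALSE)
  }
  lines <- readLines(detections)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  h <- image_size[1L]; w <- image_size[2L]
  out <- matrix(NA_real_, length(lines), 2L)
  for (i in seq_along(lines)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    if (length(f) != 5L || any(is.na(f))) {
      stop(sprintf("malformed YOLO label at line %d of '%s'", i, detections),
           call. = FALSE)
    }
    out[i, ] <- c(f[2L] * w, f[3L] * h)
  }
  data.frame(x = out[, 1L], y = out[, 2L])
}

#' Write predicted centers in the annotation CSV dialect
#'
#' Same `X,Y` format as the input annotations, so any detector's
#' predictions can be evaluated interchangeably.
#'
#' @param centers Data frame with `x`, `y`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_centers <- function(centers, path) {
  lines <- c("X,Y",
             if (nrow(centers) > 0L)
               paste(num_text(centers$x), num_text(centers$y), sep = ","))
  writeLines(lines, path)
  invisible(path)
}
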