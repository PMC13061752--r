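# Synthetic spike images with exactly known spikelet centers. The
# generator renders textured ellipses in two alternating ranks along a
# curved rachis on a noisy blue background - enough structure for the
# full pipeline (target generation, training, decoding, evaluation) to
# be exercised end-to-end with exact ground truth, without claiming
# photorealism.

#' Parameters of the synthetic spike generator
#'
#' Geometry defaults are chosen so the package's physical defaults
#' (2 mm disc radius, 6 mm boxes) are sensible on the synthetic data:
#' spikelet ellipses of 6 x 3 mm, 4 mm steps along the rachis, and
#' alternating lateral rank offsets of 2.5 mm, at 2 px/mm.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param px_per_mm Scale calibration of the rendered image.
#' @param n_spikelets Number of spikelets.
#' @param curvature_mm Lateral amplitude of the rachis curve.
#' @param rank_offset_mm Lateral offset of the alternating ranks.
#' @param spacing_mm Step between consecutive spikelets along the
#'   rachis.
#' @param blob_axes_mm `c(major, minor)` full axis lengths of each
#'   spikelet ellipse; the major axis points laterally.
#' @param spikelet_rgb Base spikelet color (golden-green).
#' @param color_jitter_sd Per-blob RGB jitter sd.
#' @param background_rgb Background color (blue).
#' @param noise_sd Per-pixel Gaussian noise sd.
#' @param annotation_jitter_mm Radial Gaussian sd of the simulated
#'   expert click error (0 = exact centers).
#' @param seed Integer seed; the generator is a pure function of
#'   (params, seed).
#' @return An object of class `spike_synth_params`.
#' @export
spike_synth_params <- function(image_size = c(256L, 96L),
                               px_per_mm = 2,
                               n_spikelets = 12L,
                               curvature_mm = 2,
                               rank_offset_mm = 2.5,
                               spacing_mm = 4,
                               blob_axes_mm = c(6, 3),
                               spikelet_rgb = c(0.78, 0.70, 0.38),
                               color_jitter_sd = 0.05,
                               background_rgb = c(0.13, 0.23, 0.55),
                               noise_sd = 0.02,
                               annotation_jitter_mm = 0,
                               seed = 1L) {
  p <- list(image_size = as.integer(image_size), px_per_mm = px_per_mm,
            n_spikelets = as.integer(n_spikelets), curvature_mm = curvature_mm,
            rank_offset_mm = rank_offset_mm, spacing_mm = spacing_mm,
            blob_axes_mm = blob_axes_mm, spikelet_rgb = spikelet_rgb,
            color_jitter_sd = color_jitter_sd, background_rgb = background_rgb,
            noise_sd = noise_sd, annotation_jitter_mm = annotation_jitter_mm,
            seed = as.integer(seed))
  if (p$n_spikelets < 0L) stop("`n_spikelets` must be >= 0", call. = FALSE)
  if (p$spacing_mm <= 0 || any(p$blob_axes_mm <= 0)) {
    stop("`spacing_mm` and `blob_axes_mm` must be positive", call. = FALSE)
  }
  if (p$annotation_jitter_mm < 0) stop("`annotation_jitter_mm` must be >= 0", call. = FALSE)
  structure(p, class = "spike_synth_params")
}

#' Render one synthetic spike image
#'
#' Spikelets are placed at `spacing_mm` steps along a sinusoidally
#' curved vertical rachis, alternating left/right of it by
#' `rank_offset_mm`, and rendered as soft-edged textured ellipses whose
#' exact geometric centers are returned as the annotation set (after
#' optional click jitter).
#'
#' @param params A [spike_synth_params()].
#' @param image_id Id given to the returned annotation set.
#' @return `list(image = H x W x 3 array in [0,1], annotations =
#'   point_annotation_set of the exact centers)`.
#' @export
generate_spike_image <- function(params = spike_synth_params(),
                                 image_id = "synthetic") {
  stopifnot(inherits(params, "spike_synth_params"))
  set.seed(params$seed)
  h <- params$image_size[1L]; w <- params$image_size[2L]
  ppm <- params$px_per_mm
  scale <- scale_calibration(ppm)
  n <- params$n_spikelets
  a_px <- params$blob_axes_mm[1L] / 2 * ppm # lateral semi-axis
  b_px <- params$blob_axes_mm[2L] / 2 * ppm # along-rachis semi-axis

  # background with pixel noise
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    img[, , ch] <- params$background_rgb[ch] +
      matrix(stats::rnorm(h * w, sd = params$noise_sd), h, w)
  }

  centers <- data.frame(x = numeric(0), y = numeric(0))
  if (n > 0L) {
    spacing_px <- params$spacing_mm * ppm
    amp_px <- params$curvature_mm * ppm
    off_px <- params$rank_offset_mm * ppm
    span <- (n - 1) * spacing_px
    y0 <- (h - 1 - span) / 2
    ys <- y0 + (0:(n - 1)) * spacing_px
    phase <- stats::runif(1, 0, 2 * pi)
    cx <- (w - 1) / 2
    arg <- function(y) pi * y / max(h - 1, 1) * 1.5 + phase
    xs <- cx + amp_px * sin(arg(ys))
    # rachis tangent (dx/dy) -> unit tangent and lateral normal
    dxdy <- amp_px * cos(arg(ys)) * pi * 1.5 / max(h - 1, 1)
    tnorm <- sqrt(1 + dxdy^2)
    tx <- dxdy / tnorm; ty <- 1 / tnorm     # tangent (x, y)
    nx <- ty; ny <- -tx                     # lateral normal
    side <- rep_len(c(1, -1), n)
    centers <- data.frame(x = xs + side * off_px * nx,
                          y = ys + side * off_px * ny)
    r_max <- max(a_px, b_px)
    if (any(centers$x - r_max < -0.5 | centers$x + r_max > w - 0.5 |
            centers$y - r_max < -0.5 | centers$y + r_max > h - 0.5)) {
      stop("spikelets exceed the image frame; increase `image_size` or reduce the geometry",
           call. = FALSE)
    }
    for (k in seq_len(n)) {
      blob_rgb <- pmin(pmax(params$spikelet_rgb +
                              stats::rnorm(3, sd = params$color_jitter_sd), 0), 1)
      cxk <- centers$x[k]; cyk <- centers$y[k]
      c0 <- max(0, floor(cxk - r_max - 1)); c1 <- min(w - 1, ceiling(cxk + r_max + 1))
      r0 <- max(0, floor(cyk - r_max - 1)); r1 <- min(h - 1, ceiling(cyk + r_max + 1))
      px <- rep(c0:c1, each = r1 - r0 + 1)
      py <- rep(r0:r1, times = c1 - c0 + 1)
      du <- (px - cxk) * nx[k] + (py - cyk) * ny[k] # lateral
      dv <- (px - cxk) * tx[k] + (py - cyk) * ty[k] # along rachis
      q <- sqrt((du / a_px)^2 + (dv / b_px)^2)
      alpha <- pmin(pmax((1 - q) / 0.15, 0), 1)
      sel <- alpha > 0
      if (!any(sel)) next
      shade <- 1 - 0.3 * q[sel]^2
      tex <- stats::rnorm(sum(sel), sd = 0.03)
      rows <- py[sel] + 1L; cols <- px[sel] + 1L
      for (ch in 1:3) {
        idx <- cbind(rows, cols)
        base <- img[, , ch][idx]
        img[, , ch][idx] <- base * (1 - alpha[sel]) +
          (blob_rgb[ch] * shade + tex) * alpha[sel]
      }
    }
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  ann <- point_annotation_set(image_id, c(h, w), centers, scale)
  if (params$annotation_jitter_mm > 0) {
    ann <- jitter_annotations(ann, params$annotation_jitter_mm,
                              seed = sample.int(.Machine$integer.max, 1L))
  }
  list(image = img, annotations = ann)
}

#' Simulate imprecise expert clicks
#'
#' Displaces every point by an isotropic Gaussian offset with standard
#' deviation `sigma_mm` per axis (so the displacement magnitude has a
#' radial Gaussian distribution), clipped to the image bounds.
#'
#' @param annotations A [point_annotation_set()].
#' @param sigma_mm Per-axis displacement sd in millimetres.
#' @param seed Integer seed.
#' @return A [point_annotation_set()] with the same number of points.
#' @export
jitter_annotations <- function(annotations, sigma_mm, seed = 1L) {
  stopifnot(inherits(annotations, "point_annotation_set"))
  if (sigma_mm < 0) stop("`sigma_mm` must be >= 0", call. = FALSE)
  if (sigma_mm == 0) return(annotations)
  n <- nrow(annotations$points)
  s_px <- mm_to_px(sigma_mm, annotations$scale)
  h <- annotations$image_size[1L]; w <- annotations$image_size[2L]
  pts <- with_preserved_rng(seed, {
    data.frame(
      x = pmin(pmax(annotations$points$x + stats::rnorm(n, sd = s_px), 0), w - 1),
      y = pmin(pmax(annotations$points$y + stats::rnorm(n, sd = s_px), 0), h - 1)
    )
  })
  point_annotation_set(annotations$image_id, annotations$image_size, pts,
                       annotations$scale)
}

#' Generate an on-disk synthetic dataset
#'
#' Writes `n_images` seeded variants (spikelet count drawn from
#' `count_range`, randomized rachis curvature and phase) in the layout
#' consumed by the rest of the pipeline: `images/<id>.png`,
#' `annotations/<id>.csv` (X,Y dialect) and `manifest.csv` with columns
#' `image_id`, `n_spikelets`, `px_per_mm`, `seed`.
#'
#' @param n_images Number of images (>= 1).
#' @param params A [spike_synth_params()] template; per-image count,
#'   curvature and seed are re-drawn from the dataset seed.
#' @param seed Dataset-level seed.
#' @param dir Output directory (created if needed).
#' @param count_range `c(min, max)` spikelet count range.
#' @return Invisibly, the manifest data frame.
#' @export
generate_dataset <- function(n_images, params = spike_synth_params(), seed = 1L,
                             dir, count_range = c(8L, 21L)) {
  if (n_images < 1L) stop("`n_images` must be >= 1", call. = FALSE)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), showWarnings = FALSE)
  set.seed(seed)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    pp <- params
    pp$n_spikelets <- sample(count_range[1L]:count_range[2L], 1L)
    pp$curvature_mm <- stats::runif(1, 0, params$curvature_mm)
    pp$seed <- sample.int(.Machine$integer.max, 1L)
    id <- sprintf("spike_%04d", i)
    g <- generate_spike_image(pp, image_id = id)
    png::writePNG(g$image, file.path(dir, "images", paste0(id, ".png")))
    write_point_annotations(g$annotations,
                            file.path(dir, "annotations", paste0(id, ".csv")))
    rows[[i]] <- data.frame(image_id = id, n_spikelets = pp$n_spikelets,
                            px_per_mm = params$px_per_mm, seed = pp$seed)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param dir Dataset directory.
#' @return List of samples (`image`, `annotations`) named by image id,
#'   with the manifest as attribute `"manifest"`.
#' @export
read_dataset <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(mf)), function(i) {
    id <- mf$image_id[i]
    img <- png::readPNG(file.path(dir, "images", paste0(id, ".png")))
    ann <- read_point_annotations(file.path(dir, "annotations", paste0(id, ".csv")),
                                  image_size = dim(img)[1:2],
                                  scale = scale_calibration(mf$px_per_mm[i]),
                                  image_id = id)
    list(image = img, annotations = ann)
  })
  names(samples) <- mf$image_id
  attr(samples, "manifest") <- mf
  samples
}
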