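# Training-time augmentation. One recipe, applied identically to the
# image, the target raster and the annotation points for geometric
# transforms, and to the image only for photometric ones. All draws
# come from R's RNG stream, so seeding the session (or the training
# run) makes the whole pipeline reproducible.

#' Augmentation recipe specification
#'
#' Defaults reproduce the training recipe the package's models are
#' tuned with: resize to a fixed geometry, then horizontal flip
#' (p = 0.5), vertical flip (p = 0.277), rotation within +/-30 degrees
#' (p = 0.735), Gaussian blur with kernel 1-3 (p = 0.25), Gaussian
#' noise (p = 0.15), brightness/contrast jitter (p = 0.5), RGB channel
#' shift of +/-15 intensity levels (p = 0.5), color jitter of
#' brightness/contrast/saturation/hue by 0.2 (p = 0.703), and
#' conversion to grayscale (p = 0.1).
#'
#' @param resize_to `c(height, width)` every sample is resized to
#'   (default `c(512, 224)`; both must be even for the network's
#'   pooling level).
#' @param hflip_p,vflip_p Flip probabilities.
#' @param rotate_limit,rotate_p Max |angle| in degrees and probability.
#' @param blur_limit,blur_p Odd kernel-size range and probability.
#' @param noise_sd,noise_p Gaussian pixel noise sd (intensity units in
#'   \[0,1\]) and probability.
#' @param brightness_limit,contrast_limit,brightness_contrast_p
#'   Brightness/contrast jitter amplitudes and probability.
#' @param rgb_shift_limit,rgb_shift_p Per-channel shift amplitude (in
#'   0-255 levels) and probability.
#' @param cj_brightness,cj_contrast,cj_saturation,cj_hue,cj_p Color
#'   jitter amplitudes and probability.
#' @param gray_p Grayscale conversion probability.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(resize_to = c(512L, 224L),
                              hflip_p = 0.5,
                              vflip_p = 0.277,
                              rotate_limit = 30, rotate_p = 0.735,
                              blur_limit = c(1L, 3L), blur_p = 0.25,
                              noise_sd = 0.03, noise_p = 0.15,
                              brightness_limit = 0.2, contrast_limit = 0.2,
                              brightness_contrast_p = 0.5,
                              rgb_shift_limit = 15, rgb_shift_p = 0.5,
                              cj_brightness = 0.2, cj_contrast = 0.2,
                              cj_saturation = 0.2, cj_hue = 0.2,
                              cj_p = 0.703,
                              gray_p = 0.1) {
  spec <- list(resize_to = as.integer(resize_to),
               hflip_p = hflip_p, vflip_p = vflip_p,
               rotate_limit = rotate_limit, rotate_p = rotate_p,
               blur_limit = as.integer(blur_limit), blur_p = blur_p,
               noise_sd = noise_sd, noise_p = noise_p,
               brightness_limit = brightness_limit,
               contrast_limit = contrast_limit,
               brightness_contrast_p = brightness_contrast_p,
               rgb_shift_limit = rgb_shift_limit, rgb_shift_p = rgb_shift_p,
               cj_brightness = cj_brightness, cj_contrast = cj_contrast,
               cj_saturation = cj_saturation, cj_hue = cj_hue, cj_p = cj_p,
               gray_p = gray_p)
  probs <- spec[grep("_p$", names(spec))]
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    stop("all probabilities must be in [0, 1]", call. = FALSE)
  }
  if (abs(spec$rotate_limit) > 180) stop("`rotate_limit` must be within +/-180", call. = FALSE)
  if (length(spec$resize_to) != 2L || any(spec$resize_to < 2L)) {
    stop("`resize_to` must be c(height, width)", call. = FALSE)
  }
  structure(spec, class = "augmentation_spec")
}

#' Build an image + target + keypoint transform from a spec
#'
#' The returned function takes an H x W x 3 image array (values in
#' \[0,1\]), optionally a target raster and a data frame of `x`/`y`
#' points, and returns the transformed triple at the `resize_to`
#' geometry. Geometric transforms (resize, flips, rotation) act
#' identically on image and target and consistently on the points
#' (points leaving the frame are dropped); photometric transforms act
#' on the image only. Binary targets are resampled nearest-neighbour,
#' continuous targets bilinearly.
#'
#' @param spec An [augmentation_spec()].
#' @param seed Optional integer; when given, the RNG is seeded before
#'   each call so the pipeline is a pure function of its inputs.
#' @return `function(image, target = NULL, points = NULL)` returning
#'   `list(image, target, points)`.
#' @export
build_augmentation_pipeline <- function(spec = augmentation_spec(), seed = NULL) {
  stopifnot(inherits(spec, "augmentation_spec"))
  function(image, target = NULL, points = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (length(dim(image)) != 3L || dim(image)[3L] != 3L) {
      stop("`image` must be an H x W x 3 array", call. = FALSE)
    }
    if (!is.null(target) &&
        !all(dim(target) == dim(image)[1:2])) {
      stop("target raster and image shapes differ", call. = FALSE)
    }
    h0 <- dim(image)[1L]; w0 <- dim(image)[2L]
    h <- spec$resize_to[1L]; w <- spec$resize_to[2L]
    binary_target <- !is.null(target) && all(target %in% c(0, 1))
    t_interp <- if (binary_target) "nearest" else "bilinear"

    image <- resize_image(image, h, w)
    if (!is.null(target)) {
      target <- if (binary_target) resize_nearest(target, h, w)
                else resize_bilinear(target, h, w)
    }
    if (!is.null(points) && nrow(points) > 0L) {
      points <- data.frame(x = (points$x + 0.5) * w / w0 - 0.5,
                           y = (points$y + 0.5) * h / h0 - 0.5)
    }

    if (stats::runif(1) < spec$hflip_p) {
      image <- image[, w:1, , drop = FALSE]
      if (!is.null(target)) target <- target[, w:1, drop = FALSE]
      if (!is.null(points)) points$x <- (w - 1) - points$x
    }
    if (stats::runif(1) < spec$vflip_p) {
      image <- image[h:1, , , drop = FALSE]
      if (!is.null(target)) target <- target[h:1, , drop = FALSE]
      if (!is.null(points)) points$y <- (h - 1) - points$y
    }
    if (stats::runif(1) < spec$rotate_p) {
      ang <- stats::runif(1, -spec$rotate_limit, spec$rotate_limit)
      for (ch in 1:3) image[, , ch] <- rotate_raster(image[, , ch], ang)
      if (!is.null(target)) target <- rotate_raster(target, ang, interp = t_interp)
      if (!is.null(points) && nrow(points) > 0L) {
        rp <- rotate_points(points$x, points$y, ang, h, w)
        keep <- rp$x >= 0 & rp$x <= w - 1 & rp$y >= 0 & rp$y <= h - 1
        points <- data.frame(x = rp$x[keep], y = rp$y[keep])
      }
    }

    if (stats::runif(1) < spec$blur_p) {
      ks <- sample(seq(spec$blur_limit[1L], spec$blur_limit[2L], by = 2L), 1L)
      if (ks >= 3L) image <- blur3(image)
    }
    if (stats::runif(1) < spec$noise_p) {
      image <- image + array(stats::rnorm(length(image), sd = spec$noise_sd), dim(image))
    }
    if (stats::runif(1) < spec$brightness_contrast_p) {
      a <- 1 + stats::runif(1, -spec$contrast_limit, spec$contrast_limit)
      b <- stats::runif(1, -spec$brightness_limit, spec$brightness_limit)
      image <- image * a + b
    }
    if (stats::runif(1) < spec$rgb_shift_p) {
      sh <- stats::runif(3, -spec$rgb_shift_limit, spec$rgb_shift_limit) / 255
      for (ch in 1:3) image[, , ch] <- image[, , ch] + sh[ch]
    }
    if (stats::runif(1) < spec$cj_p) {
      image <- color_jitter(image,
                            bf = 1 + stats::runif(1, -spec$cj_brightness, spec$cj_brightness),
                            cf = 1 + stats::runif(1, -spec$cj_contrast, spec$cj_contrast),
                            sf = 1 + stats::runif(1, -spec$cj_saturation, spec$cj_saturation),
                            hs = stats::runif(1, -spec$cj_hue, spec$cj_hue))
    }
    if (stats::runif(1) < spec$gray_p) {
      lum <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
      for (ch in 1:3) image[, , ch] <- lum
    }
    image[image < 0] <- 0; image[image > 1] <- 1
    list(image = image, target = target, points = points)
  }
}

# separable 3x3 blur with weights (0.25, 0.5, 0.25) per axis
blur3 <- function(img) {
  sm1 <- function(m) {
    h <- nrow(m)
    up <- m[c(1L, seq_len(h - 1L)), , drop = FALSE]
    dn <- m[c(seq_len(h - 1L) + 1L, h), , drop = FALSE]
    0.25 * up + 0.5 * m + 0.25 * dn
  }
  for (ch in seq_len(dim(img)[3L])) {
    m <- img[, , ch]
    img[, , ch] <- t(sm1(t(sm1(m))))
  }
  img
}

# brightness/contrast/saturation scaling plus hue rotation (hs is a
# fraction of the hue circle), applied in fixed order b, c, s, h
color_jitter <- function(img, bf = 1, cf = 1, sf = 1, hs = 0) {
  img <- img * bf
  mu <- mean(img)
  img <- (img - mu) * cf + mu
  lum <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  for (ch in 1:3) img[, , ch] <- (img[, , ch] - lum) * sf + lum
  if (hs != 0) {
    d <- dim(img)
    rgb <- matrix(pmin(pmax(as.vector(img), 0), 1), ncol = 3L)
    hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 1)
    hsv[1L, ] <- (hsv[1L, ] + hs) %% 1
    img <- array(hsv2rgb(hsv), d)
  }
  img
}

# vectorized HSV -> RGB (h, s, v rows in [0,1]); returns n x 3 matrix
hsv2rgb <- function(hsv) {
  h6 <- hsv[1L, ] * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  v <- hsv[3L, ]; s <- hsv[2L, ]
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}
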