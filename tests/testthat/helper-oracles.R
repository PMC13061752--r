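# Shared fixtures and independent oracles. Oracles are deliberately
# naive (per-pixel scans, exhaustive enumeration) and never call the
# code paths they check.

make_ann <- function(points, h = 100L, w = 100L, ppm = 10,
                     id = "fixture") {
  point_annotation_set(id, c(h, w),
                       as.data.frame(points), scale_calibration(ppm))
}

# Brute-force disc rasterization: scan every pixel, compare its center
# distance to every point.
oracle_disc_mask <- function(ann, radius_mm) {
  h <- ann$image_size[1L]; w <- ann$image_size[2L]
  r_px <- radius_mm * ann$scale$px_per_mm
  out <- matrix(0, h, w)
  pts <- ann$points
  if (nrow(pts) == 0L) return(out)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      d2 <- (pts$x - (c - 1))^2 + (pts$y - (r - 1))^2
      if (min(d2) <= r_px^2) out[r, c] <- 1
    }
  }
  out
}

# Per-pixel loop implementations of the two losses.
oracle_bce <- function(logits, target) {
  z <- as.numeric(logits); t <- as.numeric(target)
  tot <- 0
  for (i in seq_along(z)) {
    p <- 1 / (1 + exp(-z[i]))
    tot <- tot - (t[i] * log(p) + (1 - t[i]) * log(1 - p))
  }
  tot / length(z)
}

oracle_kl <- function(log_pred, target) {
  lp <- as.numeric(log_pred); t <- as.numeric(target)
  tot <- 0
  for (i in seq_along(t)) {
    if (t[i] > 0) tot <- tot + t[i] * (log(t[i]) - lp[i])
  }
  tot
}

# Exhaustive one-to-one assignment: maximum number of pairs within the
# radius, then (among those) minimum total distance. Recursion over
# true points; feasible for <= 6 per side.
oracle_match <- function(pred, true, radius_mm, scale) {
  np <- nrow(pred); nt <- nrow(true)
  if (np == 0L || nt == 0L) return(list(tp = 0L, dist = 0))
  dmm <- outer(seq_len(nt), seq_len(np), function(i, j) {
    sqrt((true$x[i] - pred$x[j])^2 + (true$y[i] - pred$y[j])^2) /
      scale$px_per_mm
  })
  best <- list(tp = 0L, dist = 0)
  recurse <- function(ti, used, tp, dist) {
    if (ti > nt) {
      if (tp > best$tp || (tp == best$tp && dist < best$dist)) {
        best <<- list(tp = tp, dist = dist)
      }
      return(invisible())
    }
    recurse(ti + 1L, used, tp, dist) # leave true point ti unmatched
    for (pj in seq_len(np)) {
      if (!used[pj] && dmm[ti, pj] <= radius_mm) {
        used[pj] <- TRUE
        recurse(ti + 1L, used, tp + 1L, dist + dmm[ti, pj])
        used[pj] <- FALSE
      }
    }
  }
  recurse(1L, logical(np), 0L, 0)
  best
}

# Random point set with a minimum pairwise separation (rejection
# sampling in pixel coordinates).
random_separated_points <- function(n, h, w, min_sep_px, margin = 2) {
  pts <- data.frame(x = numeric(0), y = numeric(0))
  tries <- 0L
  while (nrow(pts) < n && tries < 5000L) {
    tries <- tries + 1L
    cand <- c(runif(1, margin, w - 1 - margin), runif(1, margin, h - 1 - margin))
    if (nrow(pts) == 0L ||
        min(sqrt((pts$x - cand[1])^2 + (pts$y - cand[2])^2)) > min_sep_px) {
      pts <- rbind(pts, data.frame(x = cand[1], y = cand[2]))
    }
  }
  pts
}

# Small in-memory synthetic dataset as training samples.
make_samples <- function(n_images, seed, image_size = c(128L, 64L),
                         count_range = c(6L, 12L), jitter_mm = 0) {
  dir <- file.path(tempfile("ds"))
  params <- spike_synth_params(image_size = image_size, px_per_mm = 2,
                               annotation_jitter_mm = jitter_mm)
  generate_dataset(n_images, params, seed = seed, dir = dir,
                   count_range = count_range)
  samples <- read_dataset(dir)
  unlink(dir, recursive = TRUE)
  lapply(samples, function(s) list(image = s$image, annotations = s$annotations))
}
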