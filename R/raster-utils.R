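# Low-level raster helpers shared by mask generation, augmentation,
# prediction resampling and center extraction. All of them use the
# package-wide convention: x = column, y = row, 0-based, pixel centers
# at integer coordinates.

#' Label connected foreground regions (8-connectivity)
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @return Integer matrix of the same shape; 0 = background, regions
#'   numbered from 1 in first-pixel (column-major) order.
#' @export
label_components <- function(mask) {
  fg <- which(mask > 0)
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (length(fg) == 0L) return(lab)
  infg <- logical(h * w); infg[fg] <- TRUE
  vid <- integer(h * w); vid[fg] <- seq_along(fg)
  rs <- ((fg - 1L) %% h) + 1L
  cs <- ((fg - 1L) %/% h) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rn <- rs + off[1L]; cn <- cs + off[2L]
    ok <- rn >= 1L & rn <= h & cn >= 1L & cn <= w
    nb <- rn[ok] + (cn[ok] - 1L) * h
    ok2 <- infg[nb]
    if (any(ok2)) {
      edges <- c(edges, rbind(vid[fg[ok]][ok2], vid[nb][ok2]))
    }
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber so region ids follow first-pixel order
  first <- tapply(seq_along(fg), memb, min)
  rank_of <- integer(length(first))
  rank_of[order(first)] <- seq_along(first)
  lab[fg] <- rank_of[memb]
  lab
}

# Area and centroid of each labeled region; columns x, y are 0-based
# pixel coordinates of the centroid, argmax_* the region's maximum
# location in `values` (ties: smallest row, then column).
region_stats <- function(lab, values = NULL) {
  fg <- which(lab > 0)
  if (length(fg) == 0L) {
    return(data.frame(label = integer(0), area = integer(0),
                      x = numeric(0), y = numeric(0),
                      argmax_x = numeric(0), argmax_y = numeric(0),
                      max = numeric(0)))
  }
  h <- nrow(lab)
  memb <- lab[fg]
  rs <- ((fg - 1L) %% h)        # 0-based row
  cs <- ((fg - 1L) %/% h)       # 0-based col
  area <- as.integer(table(memb))
  labs <- sort(unique(memb))
  out <- data.frame(
    label = labs,
    area = area,
    x = as.numeric(tapply(cs, memb, mean)),
    y = as.numeric(tapply(rs, memb, mean))
  )
  if (!is.null(values)) {
    v <- values[fg]
    # column-major order within a region = row-then-column tie-break,
    # and which.max takes the first maximum
    pick <- tapply(seq_along(fg), memb, function(ii) ii[which.max(v[ii])])
    pick <- as.integer(pick)
    out$argmax_x <- cs[pick]
    out$argmax_y <- rs[pick]
    out$max <- v[pick]
  }
  out
}

# Bilinear resampling of a matrix to (h2, w2). Source coordinates are
# computed with the half-pixel convention so that identity sizes return
# the input unchanged.
resize_bilinear <- function(m, h2, w2) {
  h <- nrow(m); w <- ncol(m)
  if (h2 == h && w2 == w) return(m)
  xs <- pmin(pmax(((seq_len(w2) - 0.5) * w / w2) - 0.5, 0), w - 1)
  ys <- pmin(pmax(((seq_len(h2) - 0.5) * h / h2) - 0.5, 0), h - 1)
  x0 <- floor(xs); fx <- xs - x0
  y0 <- floor(ys); fy <- ys - y0
  x1 <- pmin(x0 + 1, w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  # gather the four corner grids (1-based matrix indices)
  m00 <- m[y0 + 1, x0 + 1, drop = FALSE]; m01 <- m[y0 + 1, x1 + 1, drop = FALSE]
  m10 <- m[y1 + 1, x0 + 1, drop = FALSE]; m11 <- m[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, h2, w2); wx <- matrix(fx, h2, w2, byrow = TRUE)
  m00 * (1 - wy) * (1 - wx) + m01 * (1 - wy) * wx +
    m10 * wy * (1 - wx) + m11 * wy * wx
}

resize_nearest <- function(m, h2, w2) {
  h <- nrow(m); w <- ncol(m)
  if (h2 == h && w2 == w) return(m)
  xs <- pmin(pmax(round(((seq_len(w2) - 0.5) * w / w2) - 0.5), 0), w - 1)
  ys <- pmin(pmax(round(((seq_len(h2) - 0.5) * h / h2) - 0.5), 0), h - 1)
  m[ys + 1, xs + 1, drop = FALSE]
}

resize_image <- function(img, h2, w2, method = "bilinear") {
  f <- if (method == "nearest") resize_nearest else resize_bilinear
  if (length(dim(img)) == 2L) return(f(img, h2, w2))
  out <- array(0, c(h2, w2, dim(img)[3L]))
  for (ch in seq_len(dim(img)[3L])) out[, , ch] <- f(img[, , ch], h2, w2)
  out
}

# Rotate a raster by `theta_deg` (counter-clockwise in the x-right /
# y-down pixel frame) about the image center, keeping the output size.
# Out-of-frame samples are filled with `fill`.
rotate_raster <- function(m, theta_deg, interp = c("bilinear", "nearest"),
                          fill = 0) {
  interp <- match.arg(interp)
  h <- nrow(m); w <- ncol(m)
  th <- theta_deg * pi / 180
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  xd <- rep(0:(w - 1), each = h) - cx
  yd <- rep(0:(h - 1), times = w) - cy
  # inverse mapping: sample source at R(-theta) (p - c) + c
  xs <- cos(th) * xd + sin(th) * yd + cx
  ys <- -sin(th) * xd + cos(th) * yd + cy
  out <- rep(fill, h * w)
  if (interp == "nearest") {
    xr <- round(xs); yr <- round(ys)
    ok <- xr >= 0 & xr <= w - 1 & yr >= 0 & yr <= h - 1
    out[ok] <- m[cbind(yr[ok] + 1, xr[ok] + 1)]
  } else {
    ok <- xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1
    x0 <- floor(xs[ok]); y0 <- floor(ys[ok])
    fx <- xs[ok] - x0;   fy <- ys[ok] - y0
    x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
    out[ok] <-
      m[cbind(y0 + 1, x0 + 1)] * (1 - fy) * (1 - fx) +
      m[cbind(y0 + 1, x1 + 1)] * (1 - fy) * fx +
      m[cbind(y1 + 1, x0 + 1)] * fy * (1 - fx) +
      m[cbind(y1 + 1, x1 + 1)] * fy * fx
  }
  matrix(out, h, w)
}

# Forward-rotate 0-based (x, y) points with the same convention as
# rotate_raster, so a point follows the raster content it sits on.
rotate_points <- function(x, y, theta_deg, h, w) {
  th <- theta_deg * pi / 180
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  dx <- x - cx; dy <- y - cy
  list(x = cos(th) * dx - sin(th) * dy + cx,
       y = sin(th) * dx + cos(th) * dy + cy)
}
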