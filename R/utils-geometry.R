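# Coordinate convention used throughout: images are numeric arrays H x W x 3
# (values in [0,1]), indexed [row, col, channel]; contour points are stored as
# n x 2 matrices with columns (row, col) in 0-based pixel coordinates, so the
# pixel at R index [i, j] has coordinates (i - 1, j - 1).

#' Derive a reproducible child seed from a parent seed
#'
#' Linear-congruential style mixing that keeps results inside the 32-bit
#' integer range, so one user-facing seed can drive many independent
#' deterministic draws (one per pupa, one per posture, ...).
#'
#' @param seed integer parent seed.
#' @param k integer stream index (>= 0).
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + as.double(k) * 7919 + 1) %% 2147483647)
}

#' Convert an RGB array to luminance grayscale
#'
#' Uses the Rec. 601 weights 0.299 R + 0.587 G + 0.114 B.
#'
#' @param rgb numeric array H x W x 3 in [0,1].
#' @return numeric matrix H x W.
#' @export
rgb_to_gray <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# Vectorized HSV -> RGB (h, s, v in [0,1]); returns list(r, g, b).
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Rasterize a closed polygon into a logical pixel mask
#'
#' Scanline (even-odd) fill over a grid whose pixel centers sit at integer
#' 0-based coordinates, followed by a union with the rounded boundary points
#' so that boundary pixels whose centers lie exactly on a polygon edge are
#' kept. Vertices are listed once (the closing edge is implicit).
#'
#' @param points n x 2 matrix, columns (row, col), 0-based, possibly fractional.
#' @param nrow,ncol dimensions of the target mask.
#' @return logical matrix nrow x ncol.
#' @export
polygon_mask <- function(points, nrow, ncol) {
  mask <- matrix(FALSE, nrow, ncol)
  n <- base::nrow(points)
  if (n < 3L) return(mask)
  r1 <- points[, 1]; c1 <- points[, 2]
  r2 <- points[c(2:n, 1L), 1]; c2 <- points[c(2:n, 1L), 2]
  keep <- r1 != r2                       # horizontal edges contribute nothing
  r1 <- r1[keep]; c1 <- c1[keep]; r2 <- r2[keep]; c2 <- c2[keep]
  lo <- pmin(r1, r2); hi <- pmax(r1, r2)
  for (y in max(0, floor(min(lo))):min(nrow - 1, ceiling(max(hi)))) {
    cross <- (lo <= y) & (y < hi)        # half-open rule handles shared vertices
    if (!any(cross)) next
    xs <- sort(c1[cross] + (y - r1[cross]) * (c2[cross] - c1[cross]) / (r2[cross] - r1[cross]))
    for (i in seq(1, length(xs) - 1, by = 2)) {
      a <- ceiling(xs[i]); b <- floor(xs[i + 1])
      a <- max(a, 0); b <- min(b, ncol - 1)
      if (a <= b) mask[y + 1, (a:b) + 1] <- TRUE
    }
  }
  br <- round(points[, 1]); bc <- round(points[, 2])
  ok <- br >= 0 & br < nrow & bc >= 0 & bc < ncol
  mask[cbind(br[ok] + 1, bc[ok] + 1)] <- TRUE
  mask
}

# Second-moment ellipse fit of a filled pixel mask. Returns centroid (row,
# col, 0-based), orientation angle of the major axis (radians, measured in
# the (x = col, y = row) plane), semi-axes and eccentricity. For a filled
# continuous ellipse the second moment about an axis is (semi-axis)^2 / 4,
# which is inverted here to recover the axes.
mask_ellipse_fit <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (base::nrow(idx) < 3L) stop("degenerate region: too few pixels for an ellipse fit")
  y <- idx[, 1] - 1; x <- idx[, 2] - 1
  cy <- mean(y); cx <- mean(x)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2); mu11 <- mean((x - cx) * (y - cy))
  if (abs(mu20 - mu02) < 1e-9 && abs(mu11) < 1e-9) {
    theta <- 0                          # perfect circle: ties resolve to angle 0
  } else {
    theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  }
  common <- sqrt(pmax(0, (mu20 - mu02)^2 + 4 * mu11^2))
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  if (l2 <= 1e-12) stop("degenerate (collinear) region: ellipse fit failed")
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)
  list(centroid = c(row = cy, col = cx), angle = theta,
       major = 2 * a, minor = 2 * b,
       eccentricity = sqrt(max(0, 1 - (b / a)^2)))
}

# Rotate (row, col) points about a center by angle radians (in the
# x = col, y = row plane; positive angle rotates col-axis toward row-axis).
rotate_points <- function(points, center, angle) {
  y <- points[, 1] - center[1]; x <- points[, 2] - center[2]
  ca <- cos(angle); sa <- sin(angle)
  cbind(row = center[1] + sa * x + ca * y,
        col = center[2] + ca * x - sa * y)
}

# Area of the minimum-area rotated rectangle enclosing a point set
# (rotating calipers over the convex hull).
min_area_rect <- function(points) {
  xy <- cbind(points[, 2], points[, 1])
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  n <- base::nrow(hull)
  if (n < 3L) return(0)
  best <- Inf
  for (i in seq_len(n)) {
    e <- hull[if (i == n) 1L else i + 1L, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    ux <- e / len; uy <- c(-ux[2], ux[1])
    px <- hull %*% ux; py <- hull %*% uy
    area <- (max(px) - min(px)) * (max(py) - min(py))
    if (area < best) best <- area
  }
  best
}

#' Hausdorff distance between two point sets
#'
#' @param a,b n x 2 coordinate matrices.
#' @return the symmetric Hausdorff distance in pixels.
#' @export
hausdorff_distance <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(max(min(apply(d2, 1, min)), min(apply(d2, 2, min)),
           max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}

# Bilinear resize of a grayscale matrix or RGB array via EBImage.
resize_raster <- function(x, h, w) {
  if (length(dim(x)) == 2L) {
    img <- EBImage::Image(t(x))
    out <- EBImage::resize(img, w = w, h = h)
    t(EBImage::imageData(out))
  } else {
    img <- EBImage::Image(aperm(x, c(2, 1, 3)), colormode = "Color")
    out <- EBImage::resize(img, w = w, h = h)
    aperm(EBImage::imageData(out), c(2, 1, 3))
  }
}
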