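# SD-PSF: the 37-dimensional pupal shape feature.
#
# The descriptor combines 14 global contour statistics with a 23-point
# curvature-width profile (KMM). The contour is first rotated so the fitted
# ellipse's major axis is horizontal; the KMM entry for K in 1..23 is the
# vertical chord (local "minor axis") of the filled silhouette sampled at
# horizontal position K/24 of the straight-edge bounding-rectangle width.
# Because a pupa tapers toward the tail, comparing the summed widths of the
# two profile halves (TL1 anterior, TL2 posterior) identifies head vs tail;
# when TL2 > TL1 the silhouette is mirrored so the blunt (head) end is
# always leftmost, making the feature invariant to 180-degree input
# rotations. Absolute scale is deliberately NOT normalized: body size
# carries species/sex signal.

#' Align a contour so its major axis is horizontal
#'
#' Fits an ellipse to the filled contour via second-order moments, rotates
#' the contour points about the centroid by minus the major-axis angle, and
#' records the fit parameters and the axis-aligned bounding box.
#'
#' @param contour a `pupa_contour` with at least 5 points.
#' @return an object of class `aligned_contour`: list(points, centroid,
#'   major_len, minor_len, eccentricity, angle, bbox) where bbox =
#'   c(row_min, row_max, col_min, col_max) of the rotated points.
#' @export
align_contour <- function(contour) {
  pts <- contour$points
  if (nrow(pts) < 5) stop("contour must have at least 5 points for an ellipse fit")
  r0 <- floor(min(pts[, 1])); c0 <- floor(min(pts[, 2]))
  local <- cbind(pts[, 1] - r0, pts[, 2] - c0)
  mask <- polygon_mask(local, ceiling(max(local[, 1])) + 1,
                       ceiling(max(local[, 2])) + 1)
  fit <- mask_ellipse_fit(mask)
  center <- c(fit$centroid[1] + r0, fit$centroid[2] + c0)
  rot <- rotate_points(pts, center, -fit$angle)
  bbox <- c(row_min = min(rot[, 1]), row_max = max(rot[, 1]),
            col_min = min(rot[, 2]), col_max = max(rot[, 2]))
  structure(list(points = rot, centroid = center, major_len = fit$major,
                 minor_len = fit$minor, eccentricity = fit$eccentricity,
                 angle = fit$angle, bbox = bbox),
            class = "aligned_contour")
}

# Rasterize an aligned contour into a local mask; returns list(mask, col0)
# where a mask column j corresponds to aligned column coordinate col0 + j - 1.
.aligned_mask <- function(points) {
  r0 <- floor(min(points[, 1])); c0 <- floor(min(points[, 2]))
  local <- cbind(points[, 1] - r0, points[, 2] - c0)
  list(mask = polygon_mask(local, ceiling(max(local[, 1])) + 1,
                           ceiling(max(local[, 2])) + 1),
       row0 = r0, col0 = c0)
}

# Vertical chord widths of a mask at the 23 sampling columns K/24 across a
# bounding box spanning columns [cmin, cmax] (aligned-frame coordinates).
.kmm_widths <- function(mask, col0, cmin, cmax) {
  W <- cmax - cmin
  vapply(1:23, function(K) {
    x <- cmin + K * W / 24
    j <- round(x) - col0 + 1                      # local column index
    if (j < 1 || j > ncol(mask)) return(0)
    rows <- which(mask[, j])
    if (!length(rows)) 0 else diff(range(rows)) + 1
  }, numeric(1))
}

#' Compute the 23-point KMM curvature-width profile
#'
#' Samples the vertical chord of the filled, axis-aligned silhouette at
#' horizontal positions K/24 (K = 1..23) of the bounding-box width, then
#' canonicalizes head/tail orientation: TL1 is the summed width of the
#' anterior half (K = 1..11), TL2 of the posterior half (K = 13..23), and if
#' TL2 > TL1 the silhouette is mirrored horizontally and the profile
#' recomputed, so the wider (head) end is always leftmost.
#'
#' @param aligned an `aligned_contour`.
#' @return an object of class `kmm_profile`: list(widths (23), TL1, TL2,
#'   flipped). TL1/TL2 refer to the returned (canonical) orientation.
#' @export
compute_kmm <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_contour"))
  bb <- aligned$bbox
  if ((bb["col_max"] - bb["col_min"]) < 24)
    stop("bounding box narrower than 24 px; KMM undefined")
  am <- .aligned_mask(aligned$points)
  w <- .kmm_widths(am$mask, am$col0, bb["col_min"], bb["col_max"])
  tl1 <- sum(w[1:11]); tl2 <- sum(w[13:23])
  flipped <- tl2 > tl1
  if (flipped) {
    mir <- aligned$points
    mir[, 2] <- (bb["col_min"] + bb["col_max"]) - mir[, 2]
    am <- .aligned_mask(mir)
    w <- .kmm_widths(am$mask, am$col0, bb["col_min"], bb["col_max"])
    tl1 <- sum(w[1:11]); tl2 <- sum(w[13:23])
  }
  structure(list(widths = unname(w), TL1 = unname(tl1), TL2 = unname(tl2),
                 flipped = flipped), class = "kmm_profile")
}

#' @return feature names of the 37-entry SD-PSF vector, in frozen order.
#' @rdname compute_sdpsf
#' @export
sdpsf_feature_names <- function() {
  c("perimeter", "area", "dispersity", "min_radius", "avg_radius",
    "max_radius", "radius_ratio", "major_axis", "minor_axis", "aspect_ratio",
    "rectangularity", "circularity", "compactness", "eccentricity",
    sprintf("kmm%02d", 1:23))
}

# Perimeter of a closed digital boundary. A raw chain-code polyline
# overestimates the length of smooth shapes by a few percent, so the
# boundary is lightly smoothed (circular moving average, window 5) before
# measuring arc length.
.contour_perimeter <- function(pts) {
  n <- nrow(pts)
  if (n < 5) {
    d <- pts - pts[c(2:n, 1), ]
    return(sum(sqrt(rowSums(d^2))))
  }
  sm <- pts
  for (k in c(-2L, -1L, 1L, 2L)) sm <- sm + pts[(seq_len(n) + k - 1L) %% n + 1L, ]
  sm <- sm / 5
  d <- sm - sm[c(2:n, 1), ]
  sum(sqrt(rowSums(d^2)))
}

#' Compute the 37-dimensional SD-PSF shape descriptor
#'
#' Global statistics of the pupal contour (perimeter, area, centroid-radius
#' statistics, fitted-ellipse axes, rectangularity, circularity,
#' compactness, eccentricity) followed by the 23 KMM widths from
#' [compute_kmm()]. Feature order is frozen; see [sdpsf_feature_names()].
#'
#' Definitions: radii are centroid-to-boundary-point distances
#' (radius_ratio = min/max, dispersity = sd/mean); rectangularity = area /
#' minimum-area rotated rectangle area; circularity = 4*pi*A/P^2;
#' compactness = P^2/A.
#'
#' @param contour a `pupa_contour`.
#' @return named numeric vector of length 37.
#' @export
compute_sdpsf <- function(contour) {
  pts <- contour$points
  aligned <- align_contour(contour)
  kmm <- compute_kmm(aligned)
  perim <- .contour_perimeter(pts)
  area <- contour$area_px
  cen <- contour$centroid
  radii <- sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2)
  rect <- area / min_area_rect(pts)
  out <- c(perim, area, stats::sd(radii) / mean(radii),
           min(radii), mean(radii), max(radii), min(radii) / max(radii),
           aligned$major_len, aligned$minor_len,
           aligned$major_len / aligned$minor_len,
           rect, 4 * pi * area / perim^2, perim^2 / area,
           aligned$eccentricity, kmm$widths)
  stats::setNames(out, sdpsf_feature_names())
}
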