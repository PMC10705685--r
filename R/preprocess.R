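# Segmentation and standardized cropping.
#
# The pupa is darker than the light background, so the pipeline is:
# luminance grayscale -> global Otsu threshold -> inversion (foreground =
# pupa) -> morphological opening -> connected components -> area filter
# (drops molt debris) -> largest surviving region, followed by a fixed
# 320 x 320 crop centered on the region centroid.

#' Construct a pupa contour from a filled binary mask
#'
#' Traces the outer boundary of the (single) foreground region and records
#' pixel area and centroid computed from the mask itself.
#'
#' @param mask logical or 0/1 matrix with one foreground region.
#' @return an object of class `pupa_contour`: list(points, area_px, centroid)
#'   with `points` an n x 2 (row, col) 0-based closed boundary trace.
#' @export
contour_from_mask <- function(mask) {
  m <- (mask > 0) * 1
  if (!any(m == 1)) stop("empty mask")
  oc <- EBImage::ocontour(EBImage::Image(t(m)))
  pts <- oc[[which.max(vapply(oc, nrow, 1L))]]   # (x, y) 0-based
  idx <- which(m == 1, arr.ind = TRUE)
  new_pupa_contour(cbind(row = pts[, 2], col = pts[, 1]),
                   area_px = nrow(idx),
                   centroid = c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1))
}

#' @rdname contour_from_mask
#' @param points n x 2 (row, col) 0-based boundary points.
#' @param area_px filled area in pixels; computed by rasterization if NULL.
#' @param centroid (row, col) centroid of the filled region; computed if NULL.
#' @export
new_pupa_contour <- function(points, area_px = NULL, centroid = NULL) {
  points <- as.matrix(points)
  colnames(points) <- c("row", "col")
  if (is.null(area_px) || is.null(centroid)) {
    r0 <- floor(min(points[, 1])); c0 <- floor(min(points[, 2]))
    local <- cbind(points[, 1] - r0, points[, 2] - c0)
    m <- polygon_mask(local, ceiling(max(local[, 1])) + 1,
                      ceiling(max(local[, 2])) + 1)
    idx <- which(m, arr.ind = TRUE)
    if (is.null(area_px)) area_px <- nrow(idx)
    if (is.null(centroid))
      centroid <- c(row = mean(idx[, 1]) - 1 + r0, col = mean(idx[, 2]) - 1 + c0)
  }
  if (area_px <= 0) stop("contour area must be > 0")
  structure(list(points = points, area_px = area_px, centroid = centroid),
            class = "pupa_contour")
}

# Filled mask of a contour inside an H x W frame: polygon fill plus the
# traced boundary pixels themselves.
contour_mask <- function(contour, H, W) {
  polygon_mask(contour$points, H, W)
}

#' Segment the pupa body from an image
#'
#' @param image H x W x 3 RGB array in [0,1], or a `pupa_image`.
#' @param area_threshold_frac contours with filled area below this fraction
#'   of the image area are discarded (debris filter). Default 0.02.
#' @param opening_size diameter in pixels of the elliptical structuring
#'   element used for the morphological opening. Default 5.
#' @return a `pupa_contour` of the largest surviving region.
#' @export
segment_pupa <- function(image, area_threshold_frac = 0.02, opening_size = 5) {
  if (inherits(image, "pupa_image")) image <- image$pixels
  stopifnot(length(dim(image)) == 3)
  gray <- rgb_to_gray(image)
  H <- nrow(gray); W <- ncol(gray)
  if (diff(range(gray)) < 0.02)
    stop("no pupa found: image intensity is (near-)constant")
  th <- EBImage::otsu(EBImage::Image(t(gray)))
  fg <- (gray < th) * 1                         # inversion: pupa is dark
  if (!any(fg == 1)) stop("no pupa found: nothing below threshold")
  if (mean(fg) > 0.5)
    stop("no pupa found: no minority dark region (is the background light?)")
  opened <- EBImage::opening(EBImage::Image(t(fg)),
                             EBImage::makeBrush(opening_size, "disc"))
  lab <- EBImage::bwlabel(opened)
  labm <- t(EBImage::imageData(lab))
  n <- max(labm)
  if (n < 1) stop("no pupa found: opening removed all foreground")
  areas <- tabulate(labm[labm > 0], nbins = n)
  keep <- which(areas >= area_threshold_frac * H * W)
  if (!length(keep)) stop("no pupa found: all regions below area threshold")
  winner <- keep[which.max(areas[keep])]
  out <- contour_from_mask(labm == winner)
  attr(out, "n_surviving") <- length(keep)   # regions above the area threshold
  out
}

#' Crop a fixed window centered on the pupa
#'
#' Extracts a `size` x `size` (default 320) window centered on the filled
#' contour centroid (rounded to integer pixels). Window parts outside the
#' image are padded with the background's median color. The result carries
#' the filled mask and the contour translated into crop coordinates.
#'
#' @param image H x W x 3 RGB array or `pupa_image`.
#' @param contour a `pupa_contour` in image coordinates.
#' @param size crop side length in pixels.
#' @return an object of class `crop_result`: list(crop_rgb, crop_mask,
#'   contour, offset, truncated). `offset` is the (row, col) translation from
#'   source-image to crop coordinates (crop = source - offset), 0-based.
#' @export
crop_centered <- function(image, contour, size = 320) {
  if (inherits(image, "pupa_image")) image <- image$pixels
  H <- dim(image)[1]; W <- dim(image)[2]
  ext <- c(diff(range(contour$points[, 1])), diff(range(contour$points[, 2])))
  truncated <- any(ext > size)
  if (truncated)
    warning("contour extent (", paste(round(ext), collapse = "x"),
            ") exceeds the ", size, "-px crop; mask will be truncated")
  r0 <- round(contour$centroid[1]) - size %/% 2     # 0-based top row
  c0 <- round(contour$centroid[2]) - size %/% 2
  full_mask <- contour_mask(contour, H, W)
  bg <- vapply(1:3, function(ch) stats::median(image[, , ch][!full_mask]), 0)
  crop <- array(rep(bg, each = size * size), dim = c(size, size, 3))
  mask <- matrix(FALSE, size, size)
  src_r <- max(r0, 0):min(r0 + size - 1, H - 1)
  src_c <- max(c0, 0):min(c0 + size - 1, W - 1)
  if (length(src_r) && length(src_c)) {
    crop[src_r - r0 + 1, src_c - c0 + 1, ] <- image[src_r + 1, src_c + 1, , drop = FALSE]
    mask[src_r - r0 + 1, src_c - c0 + 1] <- full_mask[src_r + 1, src_c + 1]
  }
  cpts <- cbind(row = contour$points[, 1] - r0, col = contour$points[, 2] - c0)
  ccent <- c(row = contour$centroid[1] - r0, col = contour$centroid[2] - c0)
  structure(list(crop_rgb = crop, crop_mask = mask,
                 contour = structure(list(points = cpts, area_px = contour$area_px,
                                          centroid = ccent), class = "pupa_contour"),
                 offset = c(row = r0, col = c0), truncated = truncated),
            class = "crop_result")
}
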