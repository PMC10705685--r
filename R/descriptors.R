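# Classical texture/color descriptors at fixed output dimensions:
# HOG 1296, Hu moments 7, equivalent (uniform) LBP 59, GLCM 20,
# HSV color histogram 768. All deterministic.

#' Descriptor parameterization
#'
#' Returns the fixed configuration of the five classical descriptors. The
#' HOG input is resized to 210 x 210 because with 30-px cells and 2 x 2-cell
#' blocks at single-cell stride that is the geometry that yields exactly
#' 7 x 7 cells, 6 x 6 blocks and 6*6*2*2*9 = 1296 features.
#'
#' @return nested list of descriptor parameters.
#' @export
descriptor_config <- function() {
  list(hog = list(cell_px = 30, cells_per_block = 2, bins = 9, resize_px = 210),
       glcm = list(levels = 64, angles = c(0, 45, 90, 135), distance_px = 1),
       lbp = list(radius = 1, neighbors = 8, bins = 59),
       color = list(space = "HSV", bins_per_channel = 256, masked = TRUE))
}

.as_crop <- function(crop) {
  if (inherits(crop, "crop_result")) return(crop)
  stop("expected a crop_result; run segment_pupa() + crop_centered() first")
}

#' Histogram of oriented gradients (1296 features)
#'
#' Grayscale crop resized to 210 x 210; central-difference gradients;
#' unsigned orientation quantized into 9 bins of 20 degrees; 30 x 30-px
#' cells; 2 x 2-cell blocks at one-cell stride with L2-Hys normalization
#' (clip 0.2). Output is block-major (row, then col), cell-major within a
#' block, orientation-minor: length 1296.
#'
#' @param crop a `crop_result`.
#' @return numeric vector of length 1296.
#' @export
compute_hog <- function(crop) {
  cfg <- descriptor_config()$hog
  g <- resize_raster(rgb_to_gray(.as_crop(crop)$crop_rgb),
                     cfg$resize_px, cfg$resize_px)
  n <- cfg$resize_px
  gpadc <- cbind(g[, 1], g, g[, n])
  gpadr <- rbind(g[1, ], g, g[n, ])
  gx <- (gpadc[, 3:(n + 2)] - gpadc[, 1:n]) / 2
  gy <- (gpadr[3:(n + 2), ] - gpadr[1:n, ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  bin <- pmin(floor(ang / (pi / 9)), 8)
  cells_per_side <- n / cfg$cell_px
  cr <- (row(g) - 1) %/% cfg$cell_px
  cc <- (col(g) - 1) %/% cfg$cell_px
  idx <- (cr * cells_per_side + cc) * cfg$bins + bin + 1
  hist_flat <- numeric(cells_per_side^2 * cfg$bins)
  acc <- rowsum(as.vector(mag), as.vector(idx))
  hist_flat[as.integer(rownames(acc))] <- acc
  cell_hist <- array(hist_flat, dim = c(cfg$bins, cells_per_side, cells_per_side))
  # cell_hist[bin, cell_col + 1, cell_row + 1]
  nb <- cells_per_side - 1
  out <- numeric(nb * nb * 4 * cfg$bins)
  p <- 1
  for (br in 0:(nb - 1)) for (bc in 0:(nb - 1)) {
    v <- c(cell_hist[, bc + 1, br + 1], cell_hist[, bc + 2, br + 1],
           cell_hist[, bc + 1, br + 2], cell_hist[, bc + 2, br + 2])
    nrm <- sqrt(sum(v^2) + 1e-12)
    if (nrm > 1e-6) {
      v <- pmin(v / nrm, 0.2)                    # L2-Hys
      v <- v / sqrt(sum(v^2) + 1e-12)
    } else v <- v * 0
    out[p:(p + 4 * cfg$bins - 1)] <- v
    p <- p + 4 * cfg$bins
  }
  out
}

#' Hu invariant moments of the silhouette (7 features)
#'
#' The seven classical rotation/translation/scale-invariant moment
#' combinations, computed on the binary mask (pure shape, complementary to
#' SD-PSF) and signed-log transformed: h' = -sign(h) * log10(|h| + 1e-30).
#'
#' @param mask binary matrix (e.g. `crop_result$crop_mask`).
#' @return numeric vector of length 7.
#' @export
compute_hu <- function(mask) {
  if (inherits(mask, "crop_result")) mask <- mask$crop_mask
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  y <- idx[, 1]; x <- idx[, 2]
  m00 <- length(x)
  cx <- mean(x); cy <- mean(y)
  mu <- function(p, q) sum((x - cx)^p * (y - cy)^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h <- c(h1, h2, h3, h4, h5, h6, h7)
  -sign(h) * log10(abs(h) + 1e-30)
}

# Uniform-pattern lookup table: 8-bit codes with <= 2 circular 0/1
# transitions map to 58 distinct bins (ordered by code value); all other
# codes share the 59th catch-all bin.
.lbp_uniform_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      codes <- 0:255
      trans <- vapply(codes, function(cd) {
        b <- as.integer(intToBits(cd))[1:8]
        sum(b != b[c(2:8, 1)])
      }, 0L)
      uni <- which(trans <= 2) - 1L
      t2 <- rep(59L, 256)
      t2[uni + 1L] <- seq_along(uni)
      tab <<- t2
    }
    tab
  }
})

#' Equivalent (uniform) local binary pattern histogram (59 features)
#'
#' 8-neighbor, radius-1 LBP codes (neighbor >= center, weights 2^k starting
#' East and proceeding counterclockwise), mapped to the 58 uniform patterns
#' plus one catch-all bin. The histogram is accumulated over mask pixels
#' whose full 3 x 3 neighborhood lies inside the crop, and normalized to
#' sum 1.
#'
#' @param crop a `crop_result`.
#' @return numeric vector of length 59 summing to 1.
#' @export
compute_eqlbp <- function(crop) {
  crop <- .as_crop(crop)
  g <- rgb_to_gray(crop$crop_rgb)
  H <- nrow(g); W <- ncol(g)
  # neighbor offsets (drow, dcol): E, NE, N, NW, W, SW, S, SE
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  ctr <- g[2:(H - 1), 2:(W - 1)]
  code <- matrix(0L, H - 2, W - 2)
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    nb <- g[(2 + o[1]):(H - 1 + o[1]), (2 + o[2]):(W - 1 + o[2])]
    code <- code + (nb >= ctr) * 2L^(k - 1L)
  }
  inmask <- crop$crop_mask[2:(H - 1), 2:(W - 1)]
  if (sum(inmask) < 9) stop("mask smaller than 9 pixels")
  bins <- .lbp_uniform_table()[code[inmask] + 1L]
  h <- tabulate(bins, nbins = 59)
  h / sum(h)
}

# Accumulate one symmetric normalized co-occurrence matrix and its 5 stats.
.glcm_stats <- function(q, mask, drow, dcol, levels) {
  H <- nrow(q); W <- ncol(q)
  r1 <- max(1, 1 - drow):min(H, H - drow)
  c1 <- max(1, 1 - dcol):min(W, W - dcol)
  a <- q[r1, c1]; b <- q[r1 + drow, c1 + dcol]
  ok <- mask[r1, c1] & mask[r1 + drow, c1 + dcol]
  if (!any(ok)) stop("no co-occurring pixel pairs inside the mask")
  cm <- matrix(0, levels, levels)
  tab <- table(factor(a[ok], levels = 0:(levels - 1)),
               factor(b[ok], levels = 0:(levels - 1)))
  cm <- unclass(tab) + t(unclass(tab))          # symmetric
  p <- cm / sum(cm)
  i <- row(p) - 1; j <- col(p) - 1
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  ent <- -sum(ifelse(p > 0, p * log(p), 0))
  mi <- sum(i * p); mj <- sum(j * p)
  si <- sqrt(sum((i - mi)^2 * p)); sj <- sqrt(sum((j - mj)^2 * p))
  corr <- if (si < 1e-12 || sj < 1e-12) 0 else sum((i - mi) * (j - mj) * p) / (si * sj)
  idm <- sum(p / (1 + (i - j)^2))
  c(asm = asm, contrast = contrast, entropy = ent, correlation = corr, idm = idm)
}

#' Gray-level co-occurrence matrix statistics (20 features)
#'
#' The grayscale crop is quantized to 64 levels; symmetric normalized
#' co-occurrence matrices are built at distance 1 for the four angles 0, 45,
#' 90 and 135 degrees (pairs restricted to mask pixels); for each angle the
#' angular second moment, contrast, entropy (natural log), correlation
#' (defined as 0 when a marginal variance vanishes) and inverse difference
#' moment are computed. Output is angle-major: 4 x 5 = 20 values.
#'
#' @param crop a `crop_result`.
#' @return named numeric vector of length 20.
#' @export
compute_glcm <- function(crop) {
  crop <- .as_crop(crop)
  cfg <- descriptor_config()$glcm
  g <- rgb_to_gray(crop$crop_rgb)
  q <- pmin(floor(g * cfg$levels), cfg$levels - 1)
  # offsets (drow, dcol) for 0/45/90/135 degrees at distance 1
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0), `135` = c(-1, -1))
  out <- unlist(lapply(names(offs), function(nm) {
    s <- .glcm_stats(q, crop$crop_mask, offs[[nm]][1], offs[[nm]][2], cfg$levels)
    stats::setNames(s, paste0("a", nm, "_", names(s)))
  }))
  out
}

#' Masked HSV color histogram (768 features)
#'
#' The crop is converted to HSV; hue, saturation and value are each
#' quantized into 256 bins over the pupa-mask pixels only (so the background
#' carries no class signal); each 256-bin block is normalized to sum 1 and
#' the three blocks concatenated H, S, V.
#'
#' @param crop a `crop_result`.
#' @return numeric vector of length 768.
#' @export
compute_color_hist <- function(crop) {
  crop <- .as_crop(crop)
  m <- crop$crop_mask
  if (!any(m)) stop("empty mask")
  rgb <- rbind(crop$crop_rgb[, , 1][m], crop$crop_rgb[, , 2][m],
               crop$crop_rgb[, , 3][m])
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  unlist(lapply(1:3, function(ch) {
    b <- pmin(floor(hsv[ch, ] * 256), 255)
    h <- tabulate(b + 1L, nbins = 256)
    h / sum(h)
  }))
}
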