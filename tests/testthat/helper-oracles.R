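# Independent brute-force oracles and small programmatic fixtures.
# These deliberately re-derive quantities with naive algorithms that share
# no code with the package implementations.

# Even-odd ray-casting point-in-polygon test, one pixel at a time.
oracle_point_in_polygon <- function(py, px, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# Per-column width scan of a mask: explicit double loop over pixels.
oracle_column_widths <- function(mask, cols) {
  vapply(cols, function(j) {
    lo <- NA; hi <- NA
    for (i in seq_len(nrow(mask))) {
      if (mask[i, j]) {
        if (is.na(lo)) lo <- i
        hi <- i
      }
    }
    if (is.na(lo)) 0 else hi - lo + 1
  }, numeric(1))
}

# Naive per-pixel uniform-LBP histogram on a grayscale patch (full patch,
# no mask), radius 1, neighbors ordered E, NE, N, NW, W, SW, S, SE.
oracle_lbp_hist <- function(g) {
  n_trans <- function(code) {
    b <- as.integer(intToBits(code))[1:8]
    sum(b != b[c(2:8, 1)])
  }
  uni <- which(vapply(0:255, n_trans, 0L) <= 2) - 1L
  lut <- rep(59L, 256)
  lut[uni + 1L] <- seq_along(uni)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  h <- numeric(59)
  for (i in 2:(nrow(g) - 1)) for (j in 2:(ncol(g) - 1)) {
    code <- 0
    for (k in 1:8) {
      o <- offs[[k]]
      if (g[i + o[1], j + o[2]] >= g[i, j]) code <- code + 2^(k - 1)
    }
    h[lut[code + 1]] <- h[lut[code + 1]] + 1
  }
  h / sum(h)
}

# Naive symmetric GLCM statistics at one offset by enumerating pixel pairs.
oracle_glcm_stats <- function(q, drow, dcol, levels) {
  cm <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
    i2 <- i + drow; j2 <- j + dcol
    if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
      cm[q[i, j] + 1, q[i2, j2] + 1] <- cm[q[i, j] + 1, q[i2, j2] + 1] + 1
      cm[q[i2, j2] + 1, q[i, j] + 1] <- cm[q[i2, j2] + 1, q[i, j] + 1] + 1
    }
  }
  p <- cm / sum(cm)
  iv <- row(p) - 1; jv <- col(p) - 1
  mi <- sum(iv * p); mj <- sum(jv * p)
  si <- sqrt(sum((iv - mi)^2 * p)); sj <- sqrt(sum((jv - mj)^2 * p))
  c(asm = sum(p^2),
    contrast = sum((iv - jv)^2 * p),
    entropy = -sum(p[p > 0] * log(p[p > 0])),
    correlation = if (si < 1e-12 || sj < 1e-12) 0 else
      sum((iv - mi) * (jv - mj) * p) / (si * sj),
    idm = sum(p / (1 + (iv - jv)^2)))
}

# Naive per-class one-vs-rest counting of TP/TN/FP/FN and the macro metrics.
oracle_macro_metrics <- function(y_true, y_pred, classes) {
  n <- length(y_true)
  acc <- prec <- rec <- numeric(length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    tp <- tn <- fp <- fn <- 0
    for (i in seq_len(n)) {
      t <- y_true[i] == cl; p <- y_pred[i] == cl
      if (t && p) tp <- tp + 1
      else if (!t && !p) tn <- tn + 1
      else if (!t && p) fp <- fp + 1
      else fn <- fn + 1
    }
    acc[k] <- (tp + tn) / n
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
  }
  P <- mean(prec); R <- mean(rec)
  list(accuracy = mean(acc), precision = P, recall = R,
       f1 = if (P + R > 0) 2 * P * R / (P + R) else 0)
}

# Rank-based (Mann-Whitney) AUC oracle, with midranks for ties.
oracle_rank_auc <- function(truth, score) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Rasterized ellipse mask fixture: semi-axes (a cols, b rows), optional
# rotation angle (radians) about the canvas center.
make_ellipse_mask <- function(a, b, angle = 0, pad = 30) {
  n <- 2 * ceiling(max(a, b)) + 2 * pad + 1   # odd: center on a pixel center
  cy <- cx <- (n - 1) / 2
  yy <- matrix(0:(n - 1), n, n)
  xx <- t(yy)
  u <- ((xx - cx) * cos(angle) + (yy - cy) * sin(angle)) / a
  v <- (-(xx - cx) * sin(angle) + (yy - cy) * cos(angle)) / b
  u^2 + v^2 <= 1
}

# A uniform-color crop_result built directly from a mask (no I/O).
make_flat_crop <- function(mask, rgb = c(0.4, 0.3, 0.2), bg = c(0.9, 0.9, 0.9)) {
  H <- nrow(mask); W <- ncol(mask)
  arr <- array(rep(bg, each = H * W), dim = c(H, W, 3))
  for (ch in 1:3) {
    pl <- arr[, , ch]
    pl[mask] <- rgb[ch]
    arr[, , ch] <- pl
  }
  structure(list(crop_rgb = arr, crop_mask = mask,
                 contour = contour_from_mask(mask),
                 offset = c(row = 0, col = 0), truncated = FALSE),
            class = "crop_result")
}

# Small default profile used across tests (cheap to render).
test_profile <- function(name = "tsp", len = 190, ar = 2.2, sd_len = 0,
                         sd_ar = 0) {
  species_profile(name, body_length_px = c(len, sd_len),
                  aspect_ratio = c(ar, sd_ar),
                  base_color_hsv = c(0.08, 0.55, 0.45),
                  texture_grain = 0.04)
}
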