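make_textured_crop <- function(seed = 1) {
  img <- generate_pupa(test_profile(), "female", "back", seed = seed)
  ct <- segment_pupa(img$pixels)
  crop_centered(img$pixels, ct)
}

test_that("all descriptors emit their fixed dimensions", {
  cr <- make_textured_crop()
  expect_length(compute_hog(cr), 1296)
  expect_length(compute_hu(cr), 7)
  expect_length(compute_eqlbp(cr), 59)
  expect_length(compute_glcm(cr), 20)
  expect_length(compute_color_hist(cr), 768)
})

test_that("HOG is zero on constant input and orientation-sensitive otherwise", {
  flat <- make_flat_crop(matrix(TRUE, 320, 320), rgb = c(0.5, 0.5, 0.5),
                         bg = c(0.5, 0.5, 0.5))
  expect_equal(compute_hog(flat), rep(0, 1296))
  cr <- make_textured_crop()
  rot <- cr
  rot$crop_rgb <- aperm(cr$crop_rgb, c(2, 1, 3))[, 320:1, , drop = FALSE]
  rot$crop_mask <- t(cr$crop_mask)[, 320:1]
  expect_false(isTRUE(all.equal(compute_hog(cr), compute_hog(rot))))
})

test_that("Hu moments are invariant to similarity transforms", {
  # an asymmetric blob (no reflection symmetry, so all seven moments are
  # informative), plus a scaled+rotated+translated copy of the same polygon
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  r <- 80 + 18 * sin(theta) + 9 * cos(2 * theta) + 6 * sin(3 * theta) +
    5 * sin(2 * theta)
  pts <- cbind(row = 160 + r * sin(theta), col = 160 + r * cos(theta))
  mask <- polygon_mask(pts, 320, 320)
  h0 <- compute_hu(mask)
  ang <- 0.8; s <- 1.5
  pts2 <- cbind(row = 260 + s * (r * sin(theta + ang)),
                col = 240 + s * (r * cos(theta + ang)))
  mask2 <- polygon_mask(pts2, 520, 520)
  h1 <- compute_hu(mask2)
  expect_true(all(abs(h1 - h0) / pmax(abs(h0), 1) < 0.01))
  # mirroring preserves the first six and flips the sign of the seventh
  hm <- compute_hu(mask[, ncol(mask):1])
  expect_true(all(abs(hm[1:6] - h0[1:6]) / pmax(abs(h0[1:6]), 1) < 0.01))
  expect_lt(h0[7] * hm[7], 0)
  expect_error(compute_hu(matrix(FALSE, 5, 5)), "empty")
})

test_that("uniform LBP matches a naive double-loop oracle", {
  set.seed(11)
  g <- matrix(runif(32 * 32), 32, 32)
  crop <- make_flat_crop(matrix(TRUE, 32, 32))
  for (ch in 1:3) crop$crop_rgb[, , ch] <- g   # gray image, full mask
  h <- compute_eqlbp(crop)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_equal(h, oracle_lbp_hist(g), tolerance = 1e-12)
})

test_that("LBP of a constant region concentrates in one bin", {
  crop <- make_flat_crop(matrix(TRUE, 40, 40), rgb = c(0.5, 0.5, 0.5))
  h <- compute_eqlbp(crop)
  expect_equal(max(h), 1)
  expect_equal(sum(h > 0), 1L)
  small <- make_flat_crop(rbind(cbind(matrix(TRUE, 2, 2), matrix(FALSE, 2, 38)),
                                matrix(FALSE, 38, 40)))
  expect_error(compute_eqlbp(small), "mask")
})

test_that("GLCM statistics match a brute-force pair-counting oracle", {
  set.seed(12)
  g <- matrix(runif(8 * 8), 8, 8)
  crop <- make_flat_crop(matrix(TRUE, 8, 8))
  for (ch in 1:3) crop$crop_rgb[, , ch] <- g
  got <- compute_glcm(crop)
  q <- pmin(floor(rgb_to_gray(crop$crop_rgb) * 64), 63)
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0), `135` = c(-1, -1))
  want <- unlist(lapply(names(offs), function(nm) {
    s <- oracle_glcm_stats(q, offs[[nm]][1], offs[[nm]][2], 64)
    setNames(s, paste0("a", nm, "_", names(s)))
  }))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("GLCM of a constant image is the degenerate single-cell matrix", {
  crop <- make_flat_crop(matrix(TRUE, 30, 30), rgb = c(0.5, 0.5, 0.5))
  g <- compute_glcm(crop)
  for (a in c("a0", "a45", "a90", "a135")) {
    expect_equal(unname(g[paste0(a, "_asm")]), 1)
    expect_equal(unname(g[paste0(a, "_contrast")]), 0)
    expect_equal(unname(g[paste0(a, "_entropy")]), 0)
    expect_equal(unname(g[paste0(a, "_correlation")]), 0)  # variance guard
    expect_equal(unname(g[paste0(a, "_idm")]), 1)
  }
})

test_that("color histogram blocks are mask-restricted unit histograms", {
  cr <- make_textured_crop()
  h <- compute_color_hist(cr)
  expect_equal(sum(h[1:256]), 1, tolerance = 1e-9)
  expect_equal(sum(h[257:512]), 1, tolerance = 1e-9)
  expect_equal(sum(h[513:768]), 1, tolerance = 1e-9)
  # single-color pupa: exactly one nonzero bin per channel
  flat <- make_flat_crop(make_ellipse_mask(60, 30), rgb = c(0.4, 0.3, 0.2))
  hf <- compute_color_hist(flat)
  expect_equal(sum(hf[1:256] > 0), 1L)
  expect_equal(sum(hf[257:512] > 0), 1L)
  expect_equal(sum(hf[513:768] > 0), 1L)
  # raw counts sum to the mask pixel count
  counts <- tabulate(pmin(floor(grDevices::rgb2hsv(
    rbind(cr$crop_rgb[, , 1][cr$crop_mask], cr$crop_rgb[, , 2][cr$crop_mask],
          cr$crop_rgb[, , 3][cr$crop_mask]))[1, ] * 256), 255) + 1, 256)
  expect_equal(sum(counts), sum(cr$crop_mask))
  expect_error(compute_color_hist(make_flat_crop(matrix(FALSE, 10, 10))),
               "empty")
})

test_that("masked descriptors ignore the background content", {
  cr <- make_textured_crop(seed = 5)
  altered <- cr
  # repaint the background a different uniform color
  for (ch in 1:3) {
    pl <- altered$crop_rgb[, , ch]
    pl[!altered$crop_mask] <- c(0.2, 0.6, 0.8)[ch]
    altered$crop_rgb[, , ch] <- pl
  }
  expect_equal(compute_color_hist(altered), compute_color_hist(cr))
  expect_equal(compute_glcm(altered), compute_glcm(cr), tolerance = 1e-12)
  expect_equal(compute_hu(altered), compute_hu(cr))
})
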