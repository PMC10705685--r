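test_that("alignment leaves a horizontal ellipse unchanged and fixes a rotated one", {
  horiz <- contour_from_mask(make_ellipse_mask(120, 60))
  al <- align_contour(horiz)
  expect_lt(abs(al$angle) %% pi, 0.02)
  expect_lt(max(abs(al$points - horiz$points)), 0.5)
  rot <- contour_from_mask(make_ellipse_mask(120, 60, angle = 37 * pi / 180))
  alr <- align_contour(rot)
  # same silhouette after alignment: compare bounding boxes and axes
  expect_lt(abs(alr$major_len - al$major_len), 2)
  expect_lt(abs(alr$minor_len - al$minor_len), 2)
  expect_lt(abs(diff(range(alr$points[, 2])) - diff(range(al$points[, 2]))), 2)
})

test_that("fitted eccentricity matches the closed form sqrt(1 - (b/a)^2)", {
  al <- align_contour(contour_from_mask(make_ellipse_mask(120, 60)))
  expect_lt(abs(al$eccentricity - sqrt(1 - 0.25)), 0.01)
  al2 <- align_contour(contour_from_mask(make_ellipse_mask(90, 30,
                                                           angle = 1.1)))
  expect_lt(abs(al2$eccentricity - sqrt(1 - (30 / 90)^2)), 0.01)
})

test_that("degenerate contours are rejected", {
  line <- cbind(row = rep(5, 30), col = seq(0, 29))
  expect_error(align_contour(new_pupa_contour(rbind(line, line[30:1, ] +
                                                      c(0.2, 0)), area_px = 30,
                                              centroid = c(5, 14.5))),
               "degenerate|collinear")
  expect_error(align_contour(list(points = cbind(1:3, 1:3))), "5 points")
})

test_that("KMM has 23 entries matching the analytic ellipse chord lengths", {
  al <- align_contour(contour_from_mask(make_ellipse_mask(120, 60)))
  k <- compute_kmm(al)
  expect_length(k$widths, 23)
  analytic <- 2 * 60 * sqrt(pmax(0, 1 - ((1:23) / 12 - 1)^2))
  expect_true(all(abs(k$widths - analytic) <= 2))
  expect_lt(abs(k$widths[12] - 120), 2)
})

test_that("KMM equals an independent brute-force per-column scan", {
  img <- generate_pupa(test_profile(), "female", "back", seed = 61)
  al <- align_contour(img$truth_contour)
  k <- compute_kmm(al)
  # reconstruct the canonical aligned silhouette and scan it pixel by pixel
  pts <- al$points
  if (k$flipped)
    pts[, 2] <- (al$bbox["col_min"] + al$bbox["col_max"]) - pts[, 2]
  r0 <- floor(min(pts[, 1])); c0 <- floor(min(pts[, 2]))
  local <- cbind(pts[, 1] - r0, pts[, 2] - c0)
  mask <- polygon_mask(local, ceiling(max(local[, 1])) + 1,
                       ceiling(max(local[, 2])) + 1)
  W <- al$bbox["col_max"] - al$bbox["col_min"]
  cols <- round(al$bbox["col_min"] + (1:23) * W / 24) - c0 + 1
  expect_equal(k$widths, oracle_column_widths(mask, cols))
})

test_that("left-right symmetric shapes give symmetric, flip-stable profiles", {
  al <- align_contour(contour_from_mask(make_ellipse_mask(100, 45)))
  k <- compute_kmm(al)
  expect_true(all(abs(k$widths - rev(k$widths)) <= 2))
  expect_lte(abs(k$TL1 - k$TL2), 22)   # half-sums agree to rasterization noise
})

test_that("polygon rasterization agrees with a ray-casting oracle", {
  img <- generate_pupa(test_profile(len = 120, ar = 2.0), "male", "side",
                       seed = 71)
  pts <- img$truth_contour$points
  mask <- polygon_mask(pts, 480, 480)
  set.seed(4)
  probe_r <- sample(0:479, 400, replace = TRUE)
  probe_c <- sample(0:479, 400, replace = TRUE)
  on_boundary <- function(py, px)
    min(abs(pts[, 1] - py) + abs(pts[, 2] - px)) <= 1.5
  for (t in seq_along(probe_r)) {
    py <- probe_r[t]; pc <- probe_c[t]
    if (on_boundary(py, pc)) next    # boundary pixels are implementation-defined
    expect_identical(mask[py + 1, pc + 1],
                     oracle_point_in_polygon(py, pc, pts))
  }
})

test_that("SD-PSF matches closed forms on a digital circle", {
  circ <- contour_from_mask(make_ellipse_mask(50, 50))
  f <- compute_sdpsf(circ)
  expect_length(f, 37)
  expect_named(f, sdpsf_feature_names())
  expect_lt(abs(f["circularity"] - 1), 0.05)
  expect_lt(abs(f["radius_ratio"] - 1), 0.02)
  expect_lt(f["dispersity"], 0.02)
  expect_lt(abs(f["aspect_ratio"] - 1), 0.05)
  expect_lt(abs(f["area"] - pi * 50^2) / (pi * 50^2), 0.02)
})

test_that("SD-PSF matches closed forms on a digital ellipse", {
  ell <- contour_from_mask(make_ellipse_mask(120, 60))
  f <- compute_sdpsf(ell)
  expect_lt(abs(f["aspect_ratio"] - 2), 0.05)
  expect_lt(abs(f["area"] - pi * 120 * 60) / (pi * 120 * 60), 0.02)
  expect_lt(abs(f["rectangularity"] - pi / 4), 0.03)
  expect_lt(abs(f["eccentricity"] - sqrt(0.75)), 0.01)
  expect_true(f["min_radius"] <= f["avg_radius"] &&
              f["avg_radius"] <= f["max_radius"])
})

test_that("SD-PSF is invariant to rigid motion of the contour", {
  img <- generate_pupa(test_profile(), "female", "back", seed = 81)
  ct <- img$truth_contour
  f0 <- compute_sdpsf(ct)
  # translation
  tr <- new_pupa_contour(ct$points + matrix(c(31.3, -17.7), nrow(ct$points),
                                            2, byrow = TRUE))
  ftr <- compute_sdpsf(tr)
  # rotation about the centroid by an awkward angle
  rot_pts <- pupaevision:::rotate_points(ct$points, ct$centroid, 0.61)
  frot <- compute_sdpsf(new_pupa_contour(rot_pts))
  for (f in list(ftr, frot)) {
    rel <- abs(f - f0) / pmax(abs(f0), 1e-9)
    absd <- abs(f - f0)
    expect_true(all(rel < 0.02 | absd <= 2),
                info = paste(names(f0)[!(rel < 0.02 | absd <= 2)], collapse = ","))
  }
})

test_that("180-degree rotation is canonicalized away by the TL1/TL2 flip", {
  img <- generate_pupa(test_profile(), "male", "back", seed = 91)
  ct <- img$truth_contour
  f0 <- compute_sdpsf(ct)
  rot_pts <- pupaevision:::rotate_points(ct$points, ct$centroid, pi)
  f1 <- compute_sdpsf(new_pupa_contour(rot_pts))
  rel <- abs(f1 - f0) / pmax(abs(f0), 1e-9)
  expect_true(all(rel < 0.02 | abs(f1 - f0) <= 2))
  # the KMM profile keeps the blunt head leftmost in both orientations
  expect_gte(sum(f0[15:25]), sum(f0[27:37]) - 22)
})

test_that("narrow bounding boxes are rejected for KMM", {
  tiny <- contour_from_mask(make_ellipse_mask(8, 4, pad = 5))
  expect_error(compute_kmm(align_contour(tiny)), "24")
})
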