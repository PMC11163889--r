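sp05 <- c(0.5, 0.5, 0.5)

test_that("mask centroid follows the voxel-centre convention and closed forms", {
  one <- array(FALSE, c(3, 3, 3)); one[1, 1, 1] <- TRUE
  expect_equal(mask_centroid(one, c(1, 1, 1)), c(0, 0, 0))
  cub <- array(FALSE, c(10, 10, 10)); cub[2:9, 3:8, 4:7] <- TRUE
  expect_equal(mask_centroid(cub, c(1, 2, 0.5)),
               c(mean(c(1, 8)), 2 * mean(c(2, 7)), 0.5 * mean(c(3, 6))))
  # hemisphere: centroid sits 3R/8 from the flat face
  R <- 20
  hemi <- digitize(c(-R - 1, -R - 1, -1), c(R + 1, R + 1, R + 1), sp05,
                   function(x, y, z) x^2 + y^2 + z^2 <= R^2 & z >= 0)
  cen <- mask_centroid(hemi$mask, hemi$spacing, hemi$origin)
  expect_equal(cen[3], 3 * R / 8, tolerance = 0.01 * (3 * R / 8))
  expect_lt(max(abs(cen[1:2])), 0.05)
  expect_error(mask_centroid(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), "empty")
})

test_that("mask volume counts voxels and converges to the analytic sphere volume", {
  m <- array(FALSE, c(12, 12, 7)); m[1:10, 1:10, 1:5] <- TRUE
  expect_equal(mask_volume(m, c(1, 1, 1)), 500)
  expect_error(mask_volume(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), "empty")
  r <- 10
  sph <- digitize_ellipsoid(r, r, r, rep(0.25, 3))
  expect_equal(mask_volume(sph$mask, sph$spacing), 4 / 3 * pi * r^3,
               tolerance = 0.01)
})

test_that("principal axes recover ellipsoid axes, flag isotropy, and rotate equivariantly", {
  el <- digitize_ellipsoid(15, 10, 4, sp05)
  pa <- principal_axes(el$mask, el$spacing, el$origin)
  expect_false(pa$degenerate)
  expect_lt(angle_deg(pa$axes[, 1], c(1, 0, 0)), 1)
  expect_lt(angle_deg(pa$axes[, 2], c(0, 1, 0)), 1)
  expect_lt(angle_deg(pa$axes[, 3], c(0, 0, 1)), 1)
  expect_true(all(diff(pa$moments) < 0))

  cube <- array(TRUE, c(21, 21, 21))
  expect_true(principal_axes(cube, c(1, 1, 1))$degenerate)
  expect_error(principal_axes(one <- array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)),
                              c(1, 1, 1)), "fewer than 4")

  # equivariance: digitizing the rigidly rotated shape rotates the axes
  Rm <- discmorph:::euler_rotation(c(10, 7, 20))
  elr <- digitize_cylinder(15, 10, 8, sp05, R = Rm)
  par <- principal_axes(elr$mask, elr$spacing, elr$origin)
  expect_lt(angle_deg(par$axes[, 1], Rm[, 1]), 2)
  expect_lt(angle_deg(par$axes[, 3], Rm[, 3]), 2)
})

test_that("orient_axes yields valid anatomical frames for tilted inputs", {
  anat <- diag(3)
  expect_equal(orient_axes(anat), cbind(x = c(1, 0, 0), y = c(0, 1, 0),
                                        z = c(0, 0, 1)))
  flipped <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, -1))
  expect_equal(orient_axes(flipped)[, "z"], c(0, 0, 1))
  set.seed(11)
  for (i in 1:40) {
    Rm <- discmorph:::euler_rotation(runif(3, -30, 30))
    sgn <- sample(c(-1, 1), 3, replace = TRUE)
    ax <- Rm %*% diag(sgn)
    out <- orient_axes(ax)
    expect_true(validate_disc_frame(disc_frame(c(0, 0, 0), out)))
  }
  expect_error(orient_axes(cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))),
               "perpendicular")
})

test_that("the patient sagittal plane passes through its defining centroids", {
  lv <- c(1, 5, 9, 13, 17)
  cen <- cbind(0, 0, seq(0, -160, length.out = 5))
  cen[3, 2] <- -5  # one AF displaced 5 mm posteriorly
  pl <- patient_sagittal_plane(cen, lv, l1_level = 13)
  for (i in c(1, 3, 4))
    expect_lt(abs(sum((cen[i, ] - pl$point) * pl$normal)), 1e-9)
  expect_gt(sum(pl$normal * c(-1, 0, 0)), 0)  # oriented toward scanner-left
  # exactly coplanar centroids return that plane
  cen2 <- cbind(0, c(0, -8, -12, -8, 0), seq(0, -160, length.out = 5))
  pl2 <- patient_sagittal_plane(cen2, lv, l1_level = 13)
  expect_lt(angle_deg(pl2$normal, c(1, 0, 0)), 1e-6)
  # collinear points are rejected
  cen3 <- cbind(0, 0, seq(0, -160, length.out = 5))
  expect_error(patient_sagittal_plane(cen3, lv, l1_level = 13), "collinear")
})

test_that("a posed phantom's sagittal plane is recovered within a degree", {
  ph <- make_phantom_scan(age = 12, sex = "M", n_levels = 17,
                          spacing = c(1, 1, 1), pose = c(0, 0, 10), seed = 13)
  pairs <- extract_disc_masks(ph$volume, default_label_schema(17))
  cen <- t(vapply(pairs, function(p) mask_centroid(p$af, p$spacing, p$origin),
                  numeric(3)))
  lv <- vapply(pairs, `[[`, integer(1), "level_index")
  pl <- patient_sagittal_plane(cen, lv, l1_level = 13)
  expect_lt(angle_deg(pl$normal, ph$sagittal$normal), 1)
})

test_that("frame construction aligns y with the sagittal plane and keeps it anterior", {
  el <- digitize_cylinder(15, 10, 8, sp05)
  sag <- plane3(c(0, 0, 0), c(-1, 0, 0))
  fr <- build_disc_frame(el$mask, el$spacing, el$origin, sag)
  expect_lt(angle_deg(fr$axes[, 2], c(0, 1, 0)), 0.5)  # y already in plane
  expect_true(validate_disc_frame(fr))
  # disk yawed 10 deg, plane kept sagittal: corrected y returns to anterior
  Rm <- discmorph:::euler_rotation(c(0, 0, 10))
  elr <- digitize_cylinder(15, 10, 8, sp05, R = Rm)
  frr <- build_disc_frame(elr$mask, elr$spacing, elr$origin, sag)
  expect_lt(angle_deg(frr$axes[, 2], c(0, 1, 0)), 2)
  expect_gt(sum(frr$axes[, 2] * c(0, 1, 0)), 0)
  # z parallel to the plane normal cannot be corrected
  expect_error(build_disc_frame(el$mask, el$spacing, el$origin,
                                plane3(c(0, 0, 0), c(0, 0, 1))),
               "parallel")
})

test_that("height and cross-sectional area match analytic values and survive rotation", {
  a <- 15; b <- 10; h <- 8
  el <- digitize_cylinder(a, b, h, sp05)
  sag <- plane3(c(0, 0, 0), c(-1, 0, 0))
  fr <- build_disc_frame(el$mask, el$spacing, el$origin, sag)
  H <- disc_height(el$mask, el$spacing, el$origin, fr)
  expect_equal(H, h, tolerance = 0.25 / h)  # half min-spacing
  A <- cross_sectional_area(el$mask, el$spacing, el$origin, fr)
  expect_equal(A, pi * a * b, tolerance = 0.02)
  # bounding-sphere bound
  expect_lt(H, 2 * sqrt(a^2 + b^2 + (h / 2)^2))
  # 15 degree whole-volume rotation with the corrected frame
  Rm <- discmorph:::euler_rotation(c(15, 0, 0))
  elr <- digitize_cylinder(a, b, h, sp05, R = Rm)
  sagr <- plane3(c(0, 0, 0), as.numeric(Rm %*% c(-1, 0, 0)))
  frr <- build_disc_frame(elr$mask, elr$spacing, elr$origin, sagr)
  Hr <- disc_height(elr$mask, elr$spacing, elr$origin, frr)
  Ar <- cross_sectional_area(elr$mask, elr$spacing, elr$origin, frr)
  expect_equal(Hr, H, tolerance = 0.02)
  expect_equal(Ar, A, tolerance = 0.02)
})

test_that("slenderness is the height over root-area ratio and scale invariant", {
  expect_equal(slenderness(5, 400), 0.25)
  expect_equal(slenderness(10, 100), 1.0)
  lam <- 2.7
  expect_equal(slenderness(lam * 5, lam^2 * 400), slenderness(5, 400),
               tolerance = 1e-12)
  expect_error(slenderness(0, 10), "positive")
  expect_error(slenderness(5, -1), "positive")
})

test_that("nucleus offsets report the NP displacement in anatomical directions", {
  tr0 <- disc_truth(a = 14, b = 9.8, height_mm = 6)
  ph0 <- rasterize_disc(tr0, sp05, seed = 31)
  v <- ph0$volume
  dm <- as_pair(v$labels == 1L, v$labels == 2L, v$spacing, v$origin)
  m0 <- measure_disc(dm, sagittal = ph0$sagittal)
  expect_lt(max(abs(c(m0$off_x_mm, m0$off_y_mm, m0$off_z_mm))), 0.15)
  # NP translated +2 mm anteriorly
  tr2 <- disc_truth(a = 14, b = 9.8, height_mm = 6, np_offset_mm = c(0, 2, 0))
  ph2 <- rasterize_disc(tr2, sp05, seed = 32)
  v2 <- ph2$volume
  dm2 <- as_pair(v2$labels == 1L, v2$labels == 2L, v2$spacing, v2$origin)
  m2 <- measure_disc(dm2, sagittal = ph2$sagittal)
  expect_equal(m2$off_y_mm, 2, tolerance = 0.1)
  expect_lt(abs(m2$off_x_mm), 0.2)
  expect_lt(abs(m2$off_z_mm), 0.2)
  # rigid rotation leaves the offset components unchanged within 0.2 mm
  ph3 <- rasterize_disc(tr2, sp05, pose_deg = c(10, 5, 15), seed = 33)
  v3 <- ph3$volume
  lv <- 2 * tr2$level_index
  dm3 <- as_pair(v3$labels == lv - 1L, v3$labels == lv, v3$spacing, v3$origin)
  m3 <- measure_disc(dm3, sagittal = ph3$sagittal)
  expect_lt(abs(m3$off_y_mm - m2$off_y_mm), 0.2)
  expect_lt(abs(m3$off_x_mm - m2$off_x_mm), 0.2)
  expect_lt(abs(m3$off_z_mm - m2$off_z_mm), 0.2)
})

test_that("IVD volume additivity is exact and ratios are in range", {
  tr <- disc_truth(a = 14, b = 9.8, height_mm = 6)
  ph <- rasterize_disc(tr, sp05, seed = 41)
  v <- ph$volume
  dm <- as_pair(v$labels == 1L, v$labels == 2L, v$spacing, v$origin)
  m <- measure_disc(dm, sagittal = ph$sagittal)
  expect_identical(m$V_IVD_mm3, m$V_AF_mm3 + m$V_NP_mm3)
  expect_true(m$np_ratio > 0 && m$np_ratio < 1)
  expect_equal(m$S, m$H_mm / sqrt(m$A_mm2), tolerance = 1e-12)
})
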