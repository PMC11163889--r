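tb <- default_growth_table()

test_that("disc parameter sampling is deterministic without jitter and honours construction identities", {
  t1 <- sample_disc_params(tb, 7.5, "F", 10, jitter_sd = 0)
  t2 <- sample_disc_params(tb, 7.5, "F", 10, jitter_sd = 0)
  expect_identical(t1, t2)
  g <- growth_at(tb, "low_thoracic", "F", 7.5)
  expect_equal(t1$height_mm, g$height_mm)
  expect_equal(t1$true_A, g$csa_mm2)
  expect_equal(t1$true_V_NP / t1$true_V_IVD, g$np_ratio, tolerance = 1e-9)
  # identities across a parameter sweep
  set.seed(4)
  for (i in 1:25) {
    tr <- sample_disc_params(tb, runif(1, 0, 18), sample(c("M", "F"), 1),
                             sample(1:17, 1), jitter_sd = 0.05)
    expect_equal(tr$true_S, tr$height_mm / sqrt(tr$true_A), tolerance = 1e-12)
    expect_equal(tr$true_V_IVD, tr$true_V_AF + tr$true_V_NP, tolerance = 1e-9)
    expect_true(tr$np_semi_axes[["p"]] < tr$af_semi_axes[["a"]])
    expect_true(tr$np_semi_axes[["q"]] + abs(tr$np_offset_mm[["dy"]]) <
                  tr$af_semi_axes[["b"]])
  }
})

test_that("multiplicative jitter has the stated coefficient of variation", {
  set.seed(21)
  h <- replicate(1000, sample_disc_params(tb, 12, "M", 15, jitter_sd = 0.05)$height_mm)
  expect_lt(abs(sd(h) / mean(h) - 0.05), 0.005)
  expect_equal(mean(h), growth_at(tb, "lumbar", "M", 12)$height_mm,
               tolerance = 0.01)
})

test_that("an NP that cannot fit in the AF envelope is rejected", {
  expect_error(disc_truth(a = 10, b = 7, height_mm = 5,
                          np_semi_axes = c(9.9, 6.9, 1), np_offset_mm = c(0, 2, 0)),
               "not contained")
})

test_that("voxelized volumes match the analytic elliptic-cylinder volume", {
  tr <- disc_truth(a = 15, b = 10, height_mm = 8, superellipse_n = 2,
                   z_exponent = Inf)
  expect_equal(tr$true_V_IVD, pi * 15 * 10 * 8, tolerance = 1e-12)
  ph <- rasterize_disc(tr, c(0.5, 0.5, 0.5), seed = 3)
  v <- ph$volume
  vox <- sum(v$labels > 0) * prod(v$spacing)
  expect_lt(abs(vox - pi * 15 * 10 * 8) / (pi * 15 * 10 * 8), 0.02)
})

test_that("voxelization error decreases as spacing is refined", {
  tr <- disc_truth(a = 15, b = 10, height_mm = 8, superellipse_n = 2,
                   z_exponent = Inf)
  err <- vapply(c(1.0, 0.5, 0.25), function(s) {
    # average over grid phases so a lucky coarse digitization cannot mask
    # the convergence trend
    mean(vapply(1:4, function(k) {
      ph <- rasterize_disc(tr, rep(s, 3), seed = 5 + k)
      vox <- sum(ph$volume$labels > 0) * prod(ph$volume$spacing)
      abs(vox - tr$true_V_IVD) / tr$true_V_IVD
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("a centred NP leaves the voxel centroids aligned", {
  tr <- disc_truth(a = 12, b = 8.4, height_mm = 6)
  ph <- rasterize_disc(tr, c(0.5, 0.5, 0.5), seed = 9)
  v <- ph$volume
  af <- v$labels == 1L; np <- v$labels == 2L
  c_np <- mask_centroid(np, v$spacing, v$origin)
  c_ivd <- mask_centroid(af | np, v$spacing, v$origin)
  expect_lt(max(abs(c_np - c_ivd)), 0.5 * max(v$spacing))
})

test_that("a phantom spine carries exactly two labels per level", {
  ph <- make_phantom_scan(age = 10, sex = "M", n_levels = 6, spacing = c(1, 1, 1))
  labs <- setdiff(unique(as.integer(ph$volume$labels)), 0L)
  expect_length(labs, 12)
  expect_setequal(labs, 1:12)
})

test_that("too-coarse spacing is an explicit per-level error", {
  tr <- disc_truth(a = 12, b = 8.4, height_mm = 3.5)
  expect_error(rasterize_disc(tr, c(0.5, 0.5, 2.5), seed = 1),
               "too coarse.*level 1")
})

test_that("cohort manifests honour exclusion counts and seeding", {
  man <- generate_cohort_manifest(180, reference_exclusion_counts(), seed = 42)
  expect_equal(nrow(man), 180)
  expect_equal(sum(man$exclusion_flag == "none"), 126)
  expect_equal(sum(man$exclusion_flag == "spinal_pathology"), 16)
  expect_false(anyDuplicated(man$scan_id) > 0)
  expect_equal(sum(man$sex == "M"), 90)
  man2 <- generate_cohort_manifest(180, reference_exclusion_counts(), seed = 42)
  expect_identical(man, man2)
  man3 <- generate_cohort_manifest(10, seed = 1)
  expect_true(all(man3$exclusion_flag == "none"))
  expect_error(generate_cohort_manifest(5, c(poor_quality = 6)), "exceed")
  expect_error(generate_cohort_manifest(5, c(bad_flag = 1)), "unknown")
})
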