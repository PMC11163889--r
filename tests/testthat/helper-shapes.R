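# Independent shape digitizer used as the oracle side of geometry tests:
# builds logical masks directly from a world-coordinate predicate, with no
# shared code with the package's rasterizer.

digitize <- function(lo, hi, spacing, predicate, origin_shift = NULL) {
  # default grid phase avoids the degenerate case of an analytic surface
  # passing exactly through voxel centres
  origin <- lo + (origin_shift %||% (0.37 * spacing))
  dims <- ceiling((hi - origin) / spacing) + 1
  gx <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  gy <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  gz <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  mask <- array(predicate(pts[, 1], pts[, 2], pts[, 3]), dims)
  list(mask = mask, spacing = spacing, origin = origin)
}

# elliptic cylinder |x/a|^2+|y/b|^2<=1, |z|<=h/2, optionally rotated by R
`%||%` <- function(a, b) if (is.null(a)) b else a

digitize_cylinder <- function(a, b, h, spacing, R = diag(3), pad = 2,
                              origin_shift = NULL) {
  ext <- abs(R) %*% c(a, b, h / 2) + pad
  digitize(-as.numeric(ext), as.numeric(ext), spacing, function(x, y, z) {
    loc <- cbind(x, y, z) %*% R   # world -> body (R columns are body axes)
    (loc[, 1] / a)^2 + (loc[, 2] / b)^2 <= 1 & abs(loc[, 3]) <= h / 2
  }, origin_shift)
}

digitize_ellipsoid <- function(a, b, c_, spacing, center = c(0, 0, 0), pad = 2) {
  digitize(center - c(a, b, c_) - pad, center + c(a, b, c_) + pad, spacing,
           function(x, y, z)
             ((x - center[1]) / a)^2 + ((y - center[2]) / b)^2 +
             ((z - center[3]) / c_)^2 <= 1)
}

as_pair <- function(af_mask, np_mask, spacing, origin, level_index = 1L) {
  structure(list(level_index = level_index, af = af_mask, np = np_mask,
                 spacing = spacing, origin = origin),
            class = "disc_masks")
}

angle_deg <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(min(1, abs(sum(u * v)))) * 180 / pi
}

# small phantom scan used by io/pipeline tests
make_phantom_scan <- function(age = 10, sex = "M", n_levels = 6,
                              spacing = c(1, 1, 1), jitter_sd = 0,
                              pose = c(0, 0, 0), seed = 7) {
  tb <- default_growth_table()
  truths <- with_seed_local(seed, lapply(seq_len(n_levels), function(k)
    sample_disc_params(tb, age, sex, k, jitter_sd = jitter_sd,
                       n_levels = n_levels)))
  spec <- phantom_spec(age, sex, n_levels = n_levels, spacing_mm = spacing,
                       pose_deg = pose, jitter_sd = jitter_sd, seed = seed)
  rasterize_spine(spec, truths)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
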