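# Orchestration: per-scan measurement, cohort assembly, validation.

#' Pipeline run configuration
#'
#' @param gap_close_mm Gap-closing radius passed to [close_small_gaps()]
#'   (largest gap width filled, mm).
#' @param line_step_mm Height sampling step; `NULL` = min spacing / 4.
#' @param csa_cell_mm,csa_margin_mm Cross-section sampling controls.
#' @param loess_span LOESS span for cohort growth curves.
#' @param n_levels Disk levels per scan.
#' @param l1_level L1-analog level index for the sagittal plane.
#' @param seed Master seed; all pipeline randomness derives from it.
#' @return A `run_config` list.
#' @export
run_config <- function(gap_close_mm = 1.0, line_step_mm = NULL,
                       csa_cell_mm = 0.2, csa_margin_mm = 2,
                       loess_span = 0.75, n_levels = 17, l1_level = 13,
                       seed = NULL) {
  stopifnot(gap_close_mm >= 0, csa_cell_mm > 0, csa_margin_mm >= 0,
            loess_span > 0, loess_span <= 1)
  structure(list(gap_close_mm = gap_close_mm, line_step_mm = line_step_mm,
                 csa_cell_mm = csa_cell_mm, csa_margin_mm = csa_margin_mm,
                 loess_span = loess_span, n_levels = as.integer(n_levels),
                 l1_level = as.integer(l1_level), seed = seed),
            class = "run_config")
}

#' Construct an explicit ground-truth disk
#'
#' Builds a `disc_truth` from explicit generative parameters (rather than
#' sampling them from a growth table): AF footprint semi-axes and
#' superellipse exponent, disk height, NP ellipsoid semi-axes and offset.
#' True morphometry values follow analytically: the envelope is an extruded
#' superellipse, so `true_A = c(n) * a * b`, `true_V_IVD = true_A * height`,
#' and `true_V_NP = 4/3 pi p q r`.
#'
#' @param a,b AF footprint semi-axes (mm), `a` along x (left-right).
#' @param height_mm Disk height (mm).
#' @param superellipse_n Footprint exponent (2 = exact ellipse).
#' @param z_exponent Craniocaudal envelope exponent; finite values give
#'   rounded endplate caps (default 8), `Inf` a flat-capped cylinder.
#' @param np_semi_axes NP ellipsoid semi-axes `c(p, q, r)` (mm); `NULL`
#'   defaults to a centred ellipsoid occupying about 11% of the volume.
#' @param np_offset_mm NP centre offset `c(dx, dy, dz)` in the disk frame.
#' @param level_index,age_years,sex Bookkeeping metadata.
#' @return A `disc_truth`.
#' @export
disc_truth <- function(a, b, height_mm, superellipse_n = 2.5,
                       z_exponent = .Z_EXPONENT,
                       np_semi_axes = NULL, np_offset_mm = c(0, 0, 0),
                       level_index = 1, age_years = 10, sex = "M") {
  stopifnot(a > 0, b > 0, height_mm > 0, superellipse_n > 0, z_exponent > 0)
  A <- .se_area_coef(superellipse_n) * a * b
  kvol <- .env_vol_coef(superellipse_n, z_exponent)
  if (is.null(np_semi_axes)) {
    p <- sqrt(0.11 * kvol * A / ((4 / 3) * pi * .NP_ASPECT * .NP_REL_HALF_HEIGHT))
    np_semi_axes <- c(p = p, q = .NP_ASPECT * p, r = .NP_REL_HALF_HEIGHT * height_mm)
  }
  names(np_semi_axes) <- c("p", "q", "r")
  names(np_offset_mm) <- c("dx", "dy", "dz")
  # numeric containment check: the whole NP surface must satisfy the
  # envelope inequality
  th <- seq(0, 2 * pi, length.out = 49)[-49]
  ph <- seq(-pi / 2, pi / 2, length.out = 25)
  g <- expand.grid(th = th, ph = ph)
  sx <- np_offset_mm[["dx"]] + np_semi_axes[["p"]] * cos(g$ph) * cos(g$th)
  sy <- np_offset_mm[["dy"]] + np_semi_axes[["q"]] * cos(g$ph) * sin(g$th)
  sz <- np_offset_mm[["dz"]] + np_semi_axes[["r"]] * sin(g$ph)
  sxy <- abs(sx / a)^superellipse_n + abs(sy / b)^superellipse_n
  zrel <- abs(2 * sz / height_mm)
  ok <- if (is.finite(z_exponent)) all(zrel <= 1 & sxy + zrel^z_exponent <= 1)
        else all(zrel <= 1 & sxy <= 1)
  if (!ok) stop("NP is not contained in the AF envelope")
  V_IVD <- kvol * A * height_mm
  V_NP <- (4 / 3) * pi * prod(np_semi_axes)
  structure(list(
    level_index = as.integer(level_index),
    level_group = as.character(level_group_of(level_index)),
    age_years = age_years, sex = sex,
    af_semi_axes = c(a = a, b = b), height_mm = height_mm,
    superellipse_n = superellipse_n, z_exponent = z_exponent,
    np_semi_axes = np_semi_axes, np_offset_mm = np_offset_mm,
    true_A = A, true_S = height_mm / sqrt(A),
    true_V_IVD = V_IVD, true_V_NP = V_NP, true_V_AF = V_IVD - V_NP,
    frame = NULL
  ), class = "disc_truth")
}

#' Measure every disk in one scan
#'
#' Reads (or takes) a labeled volume, resolves the schema into AF/NP pairs,
#' applies gap closing, builds the patient sagittal plane from the AF
#' centroids (falling back to the scanner mid-sagittal plane when fewer than
#' three levels resolve), and measures each disk. Per-level failures are
#' recorded in the `flags` column; the run continues.
#'
#' @param volume A [labeled_volume()] or a path to a NIfTI file.
#' @param schema Label schema (default [default_label_schema()]).
#' @param config A [run_config()].
#' @param sagittal Optional [plane3()] overriding the derived plane.
#' @return Data frame with one row per resolvable level: the
#'   [measure_disc()] columns plus `flags` (`"ok"` or the error message).
#' @export
run_scan <- function(volume, schema = NULL, config = run_config(),
                     sagittal = NULL) {
  if (is.character(volume)) volume <- read_labeled_volume(volume, schema)
  stopifnot(inherits(volume, "labeled_volume"))
  schema <- schema %||% default_label_schema(config$n_levels)
  pairs <- extract_disc_masks(volume, schema)
  sp <- volume$spacing
  for (i in seq_along(pairs)) {
    if (config$gap_close_mm > 0) {
      np2 <- close_small_gaps(pairs[[i]]$np, sp, config$gap_close_mm) & !pairs[[i]]$af
      af2 <- close_small_gaps(pairs[[i]]$af, sp, config$gap_close_mm) & !np2
      pairs[[i]]$af <- af2
      pairs[[i]]$np <- np2
    }
  }
  if (is.null(sagittal)) {
    cents <- t(vapply(pairs, function(p) mask_centroid(p$af, sp, p$origin),
                      numeric(3)))
    lvls <- vapply(pairs, `[[`, integer(1), "level_index")
    sagittal <- tryCatch(
      patient_sagittal_plane(cents, lvls, l1_level = config$l1_level),
      error = function(e) {
        message("sagittal plane fallback (", conditionMessage(e),
                "); using scanner mid-sagittal plane")
        plane3(point = colMeans(cents), normal = .DIR_LEFT)
      })
  }
  rows <- lapply(pairs, function(p) {
    res <- tryCatch(
      cbind(measure_disc(p, sagittal = sagittal,
                         line_step_mm = config$line_step_mm,
                         csa_cell_mm = config$csa_cell_mm,
                         csa_margin_mm = config$csa_margin_mm),
            flags = "ok"),
      error = function(e) data.frame(
        level_index = p$level_index, H_mm = NA_real_, A_mm2 = NA_real_,
        S = NA_real_, V_AF_mm3 = NA_real_, V_NP_mm3 = NA_real_,
        V_IVD_mm3 = NA_real_, np_ratio = NA_real_, off_x_mm = NA_real_,
        off_y_mm = NA_real_, off_z_mm = NA_real_,
        flags = conditionMessage(e)))
    res
  })
  do.call(rbind, rows)
}

#' Generate phantom volumes for a cohort manifest
#'
#' Writes one phantom per included scan (NIfTI + ground-truth JSON + schema
#' CSV) under `dir`, with per-scan seeds derived from `seed`.
#'
#' @param manifest A cohort manifest.
#' @param dir Output directory.
#' @param table Growth table (default [default_growth_table()]).
#' @param n_levels Disk levels per scan.
#' @param spacing_mm Voxel spacing.
#' @param jitter_sd Per-disk parameter noise.
#' @param seed Master seed.
#' @return Invisibly, the manifest of scans written.
#' @export
generate_phantom_cohort <- function(manifest, dir, table = default_growth_table(),
                                    n_levels = 17, spacing_mm = c(3.5, 0.5, 0.5),
                                    jitter_sd = 0.03, seed = 1) {
  inc <- apply_exclusion_filters(manifest)$included
  for (i in seq_len(nrow(inc))) {
    id <- inc$scan_id[i]
    spec <- phantom_spec(inc$age_years[i], inc$sex[i], n_levels = n_levels,
                         spacing_mm = spacing_mm,
                         jitter_sd = jitter_sd, seed = child_seed(seed, id))
    truths <- with_seed(child_seed(seed, paste0(id, "-params")),
      lapply(seq_len(n_levels), function(k)
        sample_disc_params(table, inc$age_years[i], inc$sex[i], k,
                           jitter_sd = jitter_sd, n_levels = n_levels)))
    ph <- rasterize_spine(spec, truths)
    write_phantom(ph, dir, id)
  }
  invisible(inc)
}

#' Run the measurement pipeline over a cohort
#'
#' Applies the exclusion filter, measures every included scan's volume
#' (`<scan_id>.nii.gz` under `volume_dir`), stratifies the records, and
#' computes the cohort growth-curve summaries: per level group and sex, a
#' LOESS fit of each outcome's per-subject level-group mean against age,
#' evaluated on an integer age grid, plus birth-to-18 percent changes and
#' the post hoc mid-thoracic slenderness sex comparison at ages 9--13.
#'
#' @param manifest A cohort manifest.
#' @param volume_dir Directory holding the scan volumes.
#' @param schema Label schema.
#' @param config A [run_config()].
#' @param out_dir Optional directory for CSV outputs (cohort table, LOESS
#'   curves, percent changes, tests, provenance).
#' @return List with `inventory`, `table` (cohort table), `curves`,
#'   `percent_changes`, `tests`, `provenance`.
#' @export
run_cohort <- function(manifest, volume_dir, schema = NULL,
                       config = run_config(), out_dir = NULL) {
  flt <- apply_exclusion_filters(manifest)
  inc <- flt$included
  if (nrow(inc) == 0) stop("no scans remain after exclusion filtering")
  schema <- schema %||% default_label_schema(config$n_levels)
  recs <- lapply(seq_len(nrow(inc)), function(i) {
    path <- file.path(volume_dir, paste0(inc$scan_id[i], ".nii.gz"))
    if (!file.exists(path)) stop("missing volume for scan ", inc$scan_id[i])
    cbind(scan_id = inc$scan_id[i], run_scan(path, schema, config))
  })
  records <- do.call(rbind, recs)
  tab <- stratify(records, inc, n_levels = config$n_levels)
  summaries <- summarize_cohort(tab, span = config$loess_span)
  inventory <- cohort_inventory(manifest, config$n_levels)
  provenance <- list(
    package = "discmorph",
    version = as.character(utils::packageVersion("discmorph")),
    seed = config$seed,
    config = jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null"))
  out <- c(list(inventory = inventory, table = tab), summaries,
           list(provenance = provenance))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "cohort_table.csv"), row.names = FALSE)
    utils::write.csv(summaries$curves, file.path(out_dir, "loess_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries$percent_changes,
                     file.path(out_dir, "percent_changes.csv"), row.names = FALSE)
    utils::write.csv(summaries$tests, file.path(out_dir, "tests.csv"),
                     row.names = FALSE)
    writeLines(jsonlite::toJSON(provenance, auto_unbox = TRUE),
               file.path(out_dir, "provenance.json"))
  }
  out
}

#' Cohort growth-curve summaries
#'
#' @param tab A `cohort_table`.
#' @param span LOESS span.
#' @param outcomes Outcome columns to summarise.
#' @param age_grid Ages at which LOESS curves are evaluated.
#' @return List with `curves` (long data frame of LOESS values),
#'   `percent_changes` and `tests`.
#' @export
summarize_cohort <- function(tab, span = 0.75,
                             outcomes = c("H_mm", "A_mm2", "S", "V_AF_mm3",
                                          "V_NP_mm3", "np_ratio"),
                             age_grid = 0:18) {
  ok <- tab[tab$flags == "ok" & !is.na(tab$H_mm), , drop = FALSE]
  # one dot per subject and level group: the per-subject mean across levels
  agg <- stats::aggregate(ok[, outcomes, drop = FALSE],
                          by = list(scan_id = ok$scan_id, sex = ok$sex,
                                    level_group = ok$level_group,
                                    age_years = ok$age_years),
                          FUN = mean)
  curves <- list(); pcs <- list()
  for (grp in levels(agg$level_group)) for (sx in c("M", "F")) {
    sub <- agg[agg$level_group == grp & agg$sex == sx, ]
    if (nrow(sub) < 4) next
    lo <- min(sub$age_years); hi <- max(sub$age_years)
    grid <- age_grid[age_grid >= lo & age_grid <= hi]
    for (oc in outcomes) {
      fit <- tryCatch(loess_fit(sub$age_years, sub[[oc]], span = span,
                                query = grid),
                      error = function(e) NULL)
      if (is.null(fit)) next
      curves[[length(curves) + 1]] <- data.frame(
        level_group = grp, sex = sx, outcome = oc, age = grid,
        fitted = fit$fitted)
      pc <- tryCatch(percent_change(fit, age0 = min(grid), age1 = max(grid)),
                     error = function(e) NA_real_)
      pcs[[length(pcs) + 1]] <- data.frame(
        level_group = grp, sex = sx, outcome = oc,
        age0 = min(grid), age1 = max(grid), percent = pc)
    }
  }
  mt <- agg[agg$level_group == "mid_thoracic" &
              floor(agg$age_years) >= 9 & floor(agg$age_years) <= 13, ]
  tests <- data.frame(test = character(0), t = numeric(0), df = numeric(0),
                      p = numeric(0), mean_F = numeric(0), mean_M = numeric(0))
  if (sum(mt$sex == "F") >= 2 && sum(mt$sex == "M") >= 2) {
    wt <- welch_t(mt$S[mt$sex == "F"], mt$S[mt$sex == "M"])
    tests <- data.frame(test = "mid_thoracic_slenderness_F_vs_M_ages_9_13",
                        t = wt$t, df = wt$df, p = wt$p,
                        mean_F = wt$mean_a, mean_M = wt$mean_b)
  }
  list(curves = do.call(rbind, curves) %||% data.frame(),
       percent_changes = do.call(rbind, pcs) %||% data.frame(),
       tests = tests)
}

#' Generate and measure a homogeneous group of phantom disks
#'
#' End-to-end recovery run for one (level group, sex) cell of the growth
#' table: samples `n_per_age` disks at each requested age, voxelizes each as
#' a single-disk volume, and runs the full measurement chain (gapless masks,
#' corrected frame, height, cross-sectional area, slenderness, volumes,
#' ratio, offsets). Used to check that the measurement pipeline recovers the
#' growth-curve anchors the generator was calibrated to.
#'
#' @param level_group One of [LEVEL_GROUPS].
#' @param sex `"M"` or `"F"`.
#' @param ages Ages (years) to sample at.
#' @param n_per_age Disks per age.
#' @param table Growth table.
#' @param jitter_sd Per-disk parameter noise.
#' @param spacing_mm Voxel spacing.
#' @param seed Master seed.
#' @return Data frame: one row per disk with `age`, the [measure_disc()]
#'   columns and the true `tH`, `tA`, `tS`, `tratio`.
#' @export
measure_phantom_group <- function(level_group, sex, ages, n_per_age = 20,
                                  table = default_growth_table(),
                                  jitter_sd = 0.03,
                                  spacing_mm = c(0.5, 0.5, 0.5), seed = 1) {
  level_group <- match.arg(level_group, LEVEL_GROUPS)
  # representative level index at the centre of the group
  lvl <- switch(level_group, upper_thoracic = 2L, mid_thoracic = 6L,
                low_thoracic = 10L, lumbar = 15L)
  schema <- default_label_schema(17)
  rows <- list()
  for (age in ages) for (i in seq_len(n_per_age)) {
    s <- child_seed(seed, sprintf("%s-%s-%s-%d", level_group, sex, age, i))
    tr <- with_seed(s, sample_disc_params(table, age, sex, lvl,
                                          jitter_sd = jitter_sd))
    ph <- rasterize_disc(tr, spacing_mm, seed = child_seed(s, "grid"))
    dm <- suppressMessages(extract_disc_masks(ph$volume, schema))[[1]]
    m <- measure_disc(dm, sagittal = ph$sagittal)
    rows[[length(rows) + 1]] <- cbind(
      data.frame(age = age), m,
      data.frame(tH = tr$height_mm, tA = tr$true_A, tS = tr$true_S,
                 tratio = tr$true_V_NP / tr$true_V_IVD,
                 tV_AF = tr$true_V_AF, tV_NP = tr$true_V_NP))
  }
  do.call(rbind, rows)
}

#' Validate the measurement pipeline
#'
#' Runs three self-check suites and reports measured errors against their
#' tolerances: (1) analytic oracles -- volume, centroid, height and
#' cross-sectional area of a digitized elliptic cylinder against closed
#' forms; (2) rotation invariance of the scalar measures under whole-volume
#' rotation; (3) phantom recovery -- regression of measured against true
#' height and area over a small jittered phantom sweep.
#'
#' @param config A [run_config()].
#' @param spacing_mm Voxel spacing for the checks.
#' @param n_recovery Number of phantom disks in the recovery sweep.
#' @param seed Seed for the sweep.
#' @return Data frame with columns `property`, `value`, `tolerance`, `pass`.
#' @export
validate_pipeline <- function(config = run_config(), spacing_mm = c(0.5, 0.5, 0.5),
                              n_recovery = 20, seed = 1) {
  res <- list()
  add <- function(property, value, tolerance)
    res[[length(res) + 1]] <<- data.frame(property = property, value = value,
                                          tolerance = tolerance,
                                          pass = is.finite(value) & value <= tolerance)

  tr <- disc_truth(a = 15, b = 10, height_mm = 8, superellipse_n = 2,
                   z_exponent = Inf)
  ph <- rasterize_disc(tr, spacing_mm, seed = child_seed(seed, "oracle"))
  dm <- extract_disc_masks(ph$volume, default_label_schema(1))[[1]]
  m <- measure_disc(dm, sagittal = ph$sagittal,
                    line_step_mm = config$line_step_mm,
                    csa_cell_mm = config$csa_cell_mm)
  add("volume_rel_err", abs(m$V_IVD_mm3 - tr$true_V_IVD) / tr$true_V_IVD, 0.02)
  add("csa_rel_err", abs(m$A_mm2 - tr$true_A) / tr$true_A, 0.02)
  add("height_rel_err", abs(m$H_mm - tr$height_mm) / tr$height_mm, 0.02)
  cen <- mask_centroid(dm$af | dm$np, dm$spacing, dm$origin)
  add("centroid_err_mm", vnorm(cen - ph$truths[[1]]$frame$origin), 0.5)

  ph2 <- rasterize_disc(tr, spacing_mm, pose_deg = c(10, 5, 15),
                        seed = child_seed(seed, "rot"))
  dm2 <- extract_disc_masks(ph2$volume, default_label_schema(1))[[1]]
  m2 <- measure_disc(dm2, sagittal = ph2$sagittal,
                     line_step_mm = config$line_step_mm,
                     csa_cell_mm = config$csa_cell_mm)
  add("rotation_height_rel_change", abs(m2$H_mm - m$H_mm) / m$H_mm, 0.02)
  add("rotation_csa_rel_change", abs(m2$A_mm2 - m$A_mm2) / m$A_mm2, 0.02)
  add("rotation_volume_rel_change",
      abs(m2$V_IVD_mm3 - m$V_IVD_mm3) / m$V_IVD_mm3, 0.02)

  if (n_recovery >= 4) {
    table <- default_growth_table()
    meas <- with_seed(child_seed(seed, "recovery"), {
      ages <- stats::runif(n_recovery, 0, 18)
      lvls <- sample(1:17, n_recovery, replace = TRUE)
      sexes <- sample(c("M", "F"), n_recovery, replace = TRUE)
      out <- lapply(seq_len(n_recovery), function(i) {
        tryCatch({
          t0 <- sample_disc_params(table, ages[i], sexes[i], lvls[i], jitter_sd = 0.05)
          # small random patient pose, as in real acquisitions
          p0 <- rasterize_disc(t0, spacing_mm, pose_deg = stats::runif(3, -10, 10))
          d0 <- suppressMessages(
            extract_disc_masks(p0$volume, default_label_schema(17)))[[1]]
          mm <- measure_disc(d0, sagittal = p0$sagittal,
                             line_step_mm = config$line_step_mm,
                             csa_cell_mm = config$csa_cell_mm)
          c(H = mm$H_mm, A = mm$A_mm2, tH = t0$height_mm, tA = t0$true_A)
        }, error = function(e) c(H = NA, A = NA, tH = NA, tA = NA))
      })
      stats::na.omit(as.data.frame(do.call(rbind, out)))
    })
    sH <- stats::coef(stats::lm(H ~ tH, meas))[2]
    sA <- stats::coef(stats::lm(A ~ tA, meas))[2]
    add("recovery_height_slope_err", abs(sH - 1), 0.03)
    add("recovery_csa_slope_err", abs(sA - 1), 0.03)
  }
  do.call(rbind, res)
}
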