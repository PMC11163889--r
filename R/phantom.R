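# Spine-phantom generation: labelled AF/NP volumes with known ground truth.

# Fixed disk shape: the IVD envelope is a superellipsoid
#   (|x/a|^n + |y/b|^n) + |2z/H|^m <= 1
# with in-plane exponent n = 2.5 (kidney-ish footprint, aspect b/a = 0.7) and
# craniocaudal exponent m = 8 (gently rounded endplate caps; m = Inf gives a
# flat-capped cylinder). The mid-height cross-section has area A = c(n)*a*b
# and the centroid chord height is exactly H, so slenderness H/sqrt(A) is
# analytic; the volume is k(n, m)*A*H. The NP is an ellipsoid with the same
# in-plane aspect and a craniocaudal semi-axis of 0.35 * disk height.
.SE_EXPONENT <- 2.5
.Z_EXPONENT <- 8
.AF_ASPECT <- 0.7
.NP_ASPECT <- 0.7
.NP_REL_HALF_HEIGHT <- 0.35

# area of the unit superellipse times a*b
.se_area_coef <- function(n = .SE_EXPONENT) {
  4 * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)
}

# envelope volume / (A * H): integral of (1 - u^m)^(2/n) over u in [0, 1]
.env_vol_coef <- function(n = .SE_EXPONENT, m = .Z_EXPONENT) {
  if (!is.finite(m)) return(1)
  gamma(1 + 1 / m) * gamma(1 + 2 / n) / gamma(1 + 1 / m + 2 / n)
}

#' Phantom specification
#'
#' Bundles the scan-level parameters of a synthetic spine: age, sex, number
#' of disk levels, voxel spacing, whole-spine pose and per-disk jitter.
#'
#' The default spacing emulates a sagittal acquisition: 0.5 mm in-plane with a
#' 3.5 mm slice thickness, slices stacked along the left-right (world x) axis.
#'
#' @param age_years Age in years, in [0, 18].
#' @param sex `"M"` or `"F"`.
#' @param n_levels Number of disk levels (default 17, craniocaudal).
#' @param spacing_mm Voxel spacing (mm) along world x, y, z.
#' @param pose_deg Rigid whole-spine rotation, Euler angles (degrees) about
#'   world x, y, z.
#' @param jitter_sd Per-disk multiplicative parameter noise, as a coefficient
#'   of variation (0 disables).
#' @param seed Integer seed for all randomness in the phantom, or `NULL`.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(age_years, sex, n_levels = 17,
                         spacing_mm = c(3.5, 0.5, 0.5),
                         pose_deg = c(0, 0, 0), jitter_sd = 0, seed = NULL) {
  sex <- match.arg(as.character(sex), c("M", "F"))
  stopifnot(age_years >= 0, age_years <= 18, n_levels >= 1,
            length(spacing_mm) == 3, all(spacing_mm > 0),
            length(pose_deg) == 3, jitter_sd >= 0)
  structure(list(age_years = age_years, sex = sex, n_levels = as.integer(n_levels),
                 spacing_mm = as.numeric(spacing_mm), pose_deg = as.numeric(pose_deg),
                 jitter_sd = jitter_sd, seed = seed),
            class = "phantom_spec")
}

#' Sample ground-truth parameters for one disk
#'
#' Interpolates the level group's growth curves at `age`, derives the AF
#' footprint semi-axes from the cross-sectional area (fixed aspect b/a = 0.7,
#' superellipse exponent 2.5), sizes the NP ellipsoid so that
#' V_NP / V_IVD equals the curve's np_ratio, and applies multiplicative
#' log-normal jitter with coefficient of variation `jitter_sd` to height,
#' area, ratio and nucleus offset. The IVD envelope is an extruded
#' superellipse, so the ground-truth identities `true_V_IVD = true_A * height`,
#' `true_V_IVD = true_V_AF + true_V_NP` and `true_S = height / sqrt(true_A)`
#' hold exactly.
#'
#' Jitter draws that would push the NP outside the AF envelope are clamped
#' (with a warning) rather than accepted.
#'
#' @param table A `growth_table` (see [default_growth_table()]).
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param level_index Disk level index (1-based, craniocaudal).
#' @param jitter_sd Coefficient of variation of the per-disk noise.
#' @param n_levels Levels per scan (for the level-group mapping).
#' @return A `disc_truth` object (list of generative parameters and the
#'   derived true morphometry values).
#' @export
sample_disc_params <- function(table, age, sex, level_index, jitter_sd = 0,
                               n_levels = 17) {
  stopifnot(age >= 0, age <= 18)
  grp <- as.character(level_group_of(level_index, n_levels))
  g <- growth_at(table, grp, sex, age)

  jfac <- function(k) {
    if (jitter_sd <= 0) return(rep(1, k))
    sdlog <- sqrt(log(1 + jitter_sd^2))
    # meanlog chosen so the multiplier has mean 1 and CV exactly jitter_sd
    stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  f <- jfac(4)
  H <- g$height_mm * f[1]
  A <- g$csa_mm2 * f[2]
  rho <- g$np_ratio * f[3]
  dy <- g$np_offset_y_mm * f[4]

  coef <- .se_area_coef()
  kvol <- .env_vol_coef()
  a <- sqrt(A / (.AF_ASPECT * coef))
  b <- .AF_ASPECT * a
  np_vol_coef <- (4 / 3) * pi * .NP_ASPECT * .NP_REL_HALF_HEIGHT  # V_NP = coef * p^2 * H
  fit_p <- function(rho) sqrt(rho * kvol * A / np_vol_coef)

  p <- fit_p(rho)
  q <- .NP_ASPECT * p
  r <- .NP_REL_HALF_HEIGHT * H
  # containment: with the rounded-cap envelope, max(p/a, (q+|dy|)/b) <= 0.97
  # keeps the whole NP ellipsoid inside (see disc_truth())
  clamped <- FALSE
  rho_max <- (0.97 * a)^2 * np_vol_coef / (kvol * A)
  if (rho > rho_max) { rho <- rho_max; p <- fit_p(rho); q <- .NP_ASPECT * p; clamped <- TRUE }
  dy_max <- 0.97 * b - q
  if (abs(dy) > dy_max) { dy <- sign(dy) * max(dy_max, 0); clamped <- TRUE }
  if (clamped)
    warning(sprintf("level %d: jittered NP exceeded the AF envelope; parameters clamped",
                    level_index))

  V_IVD <- kvol * A * H
  V_NP <- rho * V_IVD
  structure(list(
    level_index = as.integer(level_index), level_group = grp,
    age_years = age, sex = sex,
    af_semi_axes = c(a = a, b = b), height_mm = H,
    superellipse_n = .SE_EXPONENT, z_exponent = .Z_EXPONENT,
    np_semi_axes = c(p = p, q = q, r = r),
    np_offset_mm = c(dx = 0, dy = dy, dz = 0),
    true_A = A, true_S = H / sqrt(A),
    true_V_IVD = V_IVD, true_V_NP = V_NP, true_V_AF = V_IVD - V_NP,
    frame = NULL
  ), class = "disc_truth")
}

# Disc centres and anatomical frames along a fixed two-arc sagittal profile
# (thoracic kyphosis 30 deg, lumbar lordosis 40 deg), walked craniocaudally.
.spine_path <- function(truths) {
  n <- length(truths)
  n_thor <- max(1, round(12 / 17 * n))
  # tangent angle in the sagittal plane (deg): + = caudal direction tilted
  # posteriorly; thoracic +15 -> -15 (kyphosis), lumbar -15 -> +25 (lordosis)
  alpha <- numeric(n)
  if (n_thor > 1) alpha[1:n_thor] <- seq(15, -15, length.out = n_thor)
  if (n > n_thor) alpha[(n_thor + 1):n] <- seq(-15, 25, length.out = n - n_thor + 1)[-1]
  alpha <- alpha * pi / 180
  centers <- matrix(0, n, 3)
  pos <- c(0, 0, 0)
  for (k in seq_len(n)) {
    centers[k, ] <- pos
    pitch <- max(3.2 * truths[[k]]$height_mm, 10)
    pos <- pos + pitch * c(0, -sin(alpha[k]), -cos(alpha[k]))  # walk caudally
  }
  frames <- lapply(seq_len(n), function(k) {
    ca <- cos(alpha[k]); sa <- sin(alpha[k])
    z <- c(0, sa, ca)        # cranial
    y <- c(0, ca, -sa)       # anterior
    x <- cross3(y, z)        # completes the right-handed triad
    cbind(x, y, z)
  })
  list(centers = centers, frames = frames)
}

#' Voxelize a set of disks into a labeled volume
#'
#' Stacks the disks along a curved (sagittally S-shaped) spine axis,
#' voxelizes the AF (superellipse-cylinder envelope minus the NP region) and
#' the NP (offset ellipsoid) at the requested spacing and applies the
#' whole-spine pose. Label ids follow the schema AF of level k = 2k-1,
#' NP of level k = 2k. The voxel grid origin receives a seeded uniform
#' sub-voxel offset, so the digitization phase of each phantom is random --
#' as it is for a patient lying in a scanner.
#'
#' @param spec A `phantom_spec`.
#' @param truths List of `disc_truth` objects (one per level, cranial first).
#' @return A list with `volume` (a [labeled_volume()]), `truths` (inputs with
#'   their post-pose `frame`: `origin` and 3x3 `axes` columns x, y, z), and
#'   `sagittal` (the true posed mid-sagittal [plane3()], normal pointing left).
#' @export
rasterize_spine <- function(spec, truths) {
  stopifnot(inherits(spec, "phantom_spec"), length(truths) >= 1)
  with_seed(child_seed(spec$seed, "rasterize"), {
    path <- .spine_path(truths)
    R <- euler_rotation(spec$pose_deg)
    mid <- colMeans(path$centers)
    centers <- t(R %*% (t(path$centers) - mid))
    frames <- lapply(path$frames, function(F) R %*% F)
    spacing <- spec$spacing_mm

    # representability check before allocating anything
    for (k in seq_along(truths)) {
      u <- frames[[k]][, 3]
      step_along <- sum(abs(u) * spacing)
      if (truths[[k]]$height_mm < 2 * step_along)
        stop(sprintf("spacing too coarse to represent the disk at level %d (height %.2f mm, ~%.2f mm across slices)",
                     truths[[k]]$level_index, truths[[k]]$height_mm, step_along))
    }

    half_extents <- function(k) {
      tr <- truths[[k]]
      loc <- c(tr$af_semi_axes[["a"]], tr$af_semi_axes[["b"]], tr$height_mm / 2)
      abs(frames[[k]]) %*% loc
    }
    ext <- vapply(seq_along(truths), half_extents, numeric(3))
    lo <- apply(centers - t(ext), 2, min) - 2 - spacing
    hi <- apply(centers + t(ext), 2, max) + 2
    origin <- lo + stats::runif(3, 0, 1) * spacing
    dims <- pmax(ceiling((hi - origin) / spacing) + 1L, 2L)
    labels <- array(0L, dims)

    for (k in seq_along(truths)) {
      tr <- truths[[k]]
      Fk <- frames[[k]]
      ck <- centers[k, ]
      he <- as.numeric(half_extents(k)) + 1
      i0 <- pmax(floor((ck - he - origin) / spacing), 0)
      i1 <- pmin(ceiling((ck + he - origin) / spacing), dims - 1)
      ii <- seq(i0[1], i1[1]); jj <- seq(i0[2], i1[2]); kk <- seq(i0[3], i1[3])
      gx <- origin[1] + ii * spacing[1]
      gy <- origin[2] + jj * spacing[2]
      gz <- origin[3] + kk * spacing[3]
      pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
      loc <- (pts - matrix(ck, nrow(pts), 3, byrow = TRUE)) %*% Fk  # = t(Fk) %*% d
      a <- tr$af_semi_axes[["a"]]; b <- tr$af_semi_axes[["b"]]
      n <- tr$superellipse_n
      m <- tr$z_exponent %||% Inf
      sxy <- abs(loc[, 1] / a)^n + abs(loc[, 2] / b)^n
      zrel <- abs(2 * loc[, 3] / tr$height_mm)
      env <- if (is.finite(m)) zrel <= 1 & sxy + zrel^m <= 1
             else zrel <= 1 & sxy <= 1
      off <- tr$np_offset_mm
      s <- tr$np_semi_axes
      np <- env &
        ((loc[, 1] - off[["dx"]]) / s[["p"]])^2 +
        ((loc[, 2] - off[["dy"]]) / s[["q"]])^2 +
        ((loc[, 3] - off[["dz"]]) / s[["r"]])^2 <= 1
      lab <- integer(nrow(pts))
      lab[env] <- 2L * tr$level_index - 1L
      lab[np] <- 2L * tr$level_index
      sub <- array(lab, c(length(ii), length(jj), length(kk)))
      block <- labels[ii + 1, jj + 1, kk + 1, drop = FALSE]
      block[sub != 0L] <- sub[sub != 0L]
      labels[ii + 1, jj + 1, kk + 1] <- block
    }

    truths <- lapply(seq_along(truths), function(k) {
      tr <- truths[[k]]
      tr$frame <- list(origin = centers[k, ], axes = frames[[k]])
      tr
    })
    vol <- labeled_volume(labels, spacing, origin)
    sag <- plane3(point = colMeans(centers), normal = as.numeric(R %*% c(-1, 0, 0)))
    list(volume = vol, truths = truths, sagittal = sag)
  })
}

#' Voxelize a single disk
#'
#' Convenience wrapper around [rasterize_spine()] for one `disc_truth`.
#'
#' @inheritParams rasterize_spine
#' @param truth A single `disc_truth`.
#' @param spacing_mm Voxel spacing (mm).
#' @param pose_deg Rigid rotation (Euler degrees) applied to the disk.
#' @param seed Seed controlling the sub-voxel grid phase.
#' @return As [rasterize_spine()].
#' @export
rasterize_disc <- function(truth, spacing_mm = c(0.5, 0.5, 0.5),
                           pose_deg = c(0, 0, 0), seed = NULL) {
  spec <- phantom_spec(age_years = truth$age_years, sex = truth$sex, n_levels = 1,
                       spacing_mm = spacing_mm, pose_deg = pose_deg, seed = seed)
  rasterize_spine(spec, list(truth))
}

#' Exclusion-flag vocabulary
#'
#' The closed set of cohort exclusion reasons used in manifests: scans can be
#' excluded because the spine was not fully imaged, no sagittal series was
#' available, scan quality was poor, spinal pathology was present, the
#' patient was malpositioned, the scan was a brain MRI, or slice thickness
#' was improper.
#'
#' @format Character vector; `"none"` marks included scans.
#' @export
EXCLUSION_FLAGS <- c("none", "spine_not_fully_imaged", "no_sagittal",
                     "poor_quality", "spinal_pathology", "malposition",
                     "brain_mri", "improper_slice_thickness")

#' Reference exclusion counts
#'
#' Exclusion-reason counts of the 180-scan pediatric MRI database the phantom
#' cohort emulates (54 scans excluded, 126 included).
#'
#' @return Named integer vector over the non-`"none"` [EXCLUSION_FLAGS].
#' @export
reference_exclusion_counts <- function() {
  c(spine_not_fully_imaged = 13L, no_sagittal = 6L, poor_quality = 11L,
    spinal_pathology = 16L, malposition = 1L, brain_mri = 3L,
    improper_slice_thickness = 4L)
}

#' Generate a synthetic cohort manifest
#'
#' @param n_total Total number of scans.
#' @param exclusion_counts Named vector mapping exclusion flags (non-`"none"`
#'   [EXCLUSION_FLAGS]) to counts; their sum must not exceed `n_total`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A `cohort_manifest` data frame with columns `scan_id`,
#'   `age_years` (uniform on [0, 18]), `sex` (balanced M/F) and
#'   `exclusion_flag`.
#' @export
generate_cohort_manifest <- function(n_total, exclusion_counts = NULL, seed = NULL) {
  stopifnot(n_total >= 1)
  if (is.null(exclusion_counts)) exclusion_counts <- integer(0)
  if (length(exclusion_counts) > 0) {
    bad <- setdiff(names(exclusion_counts), setdiff(EXCLUSION_FLAGS, "none"))
    if (length(bad) > 0 || is.null(names(exclusion_counts)))
      stop("unknown exclusion flags: ", paste(bad, collapse = ", "))
  }
  if (sum(exclusion_counts) > n_total)
    stop("exclusion counts exceed the total number of scans")
  with_seed(seed, {
    flags <- rep("none", n_total)
    pool <- sample.int(n_total)
    at <- 0
    for (f in names(exclusion_counts)) {
      cnt <- exclusion_counts[[f]]
      if (cnt > 0) flags[pool[at + seq_len(cnt)]] <- f
      at <- at + cnt
    }
    sexes <- sample(rep(c("M", "F"), length.out = n_total))
    man <- data.frame(
      scan_id = sprintf("scan%04d", seq_len(n_total)),
      age_years = stats::runif(n_total, 0, 18),
      sex = sexes,
      exclusion_flag = factor(flags, levels = EXCLUSION_FLAGS),
      stringsAsFactors = FALSE
    )
    class(man) <- c("cohort_manifest", "data.frame")
    man
  })
}

#' Write a phantom to disk
#'
#' Writes the label volume as NIfTI, the ground truth as a JSON sidecar and
#' the label schema as CSV.
#'
#' @param phantom Result of [rasterize_spine()].
#' @param dir Output directory (created if missing).
#' @param scan_id Basename for the files.
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir, scan_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vol_path <- file.path(dir, paste0(scan_id, ".nii.gz"))
  write_labeled_volume(phantom$volume, vol_path)
  gt_path <- file.path(dir, paste0(scan_id, "_truth.json"))
  jsonlite::write_json(lapply(phantom$truths, function(tr) {
    tr$frame$axes <- as.numeric(tr$frame$axes)
    unclass(tr)
  }), gt_path, auto_unbox = TRUE, digits = NA)
  schema <- default_label_schema(length(phantom$truths))
  sch_path <- file.path(dir, paste0(scan_id, "_schema.csv"))
  write_label_schema(schema, sch_path)
  invisible(c(volume = vol_path, truth = gt_path, schema = sch_path))
}
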