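# Disk geometry: centroids, volumes, inertia-axis frames, sagittal rotation
# correction, height, cross-sectional area, slenderness, nucleus offset.
#
# All geometry is computed in scanner (RAS) millimetre space with the
# voxel-centre convention: world = origin + index * spacing, indices 0-based.

#' Plane in 3D
#'
#' @param point A point on the plane (mm).
#' @param normal Plane normal (normalised internally).
#' @return A `plane3` object with unit `normal`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = unit(as.numeric(normal))),
            class = "plane3")
}

#' Disk coordinate frame
#'
#' Right-handed orthonormal triad anchored at the AF centroid: `z` points
#' cranially, `y` anteriorly, and `x = y x z` completes the right-handed
#' system (so +x is the anatomical right; leftward offsets are reported with
#' a sign flip, see [nucleus_offset()]).
#'
#' @param origin Frame origin (AF centroid, mm).
#' @param axes 3x3 matrix with columns x, y, z.
#' @return A `disc_frame` object.
#' @export
disc_frame <- function(origin, axes) {
  f <- structure(list(origin = as.numeric(origin), axes = axes), class = "disc_frame")
  validate_disc_frame(f)
  f
}

#' @rdname disc_frame
#' @param frame A `disc_frame` to validate: pairwise orthogonality below
#'   1e-9, determinant +1, `z` toward scanner-cranial and `y` toward
#'   scanner-anterior.
#' @export
validate_disc_frame <- function(frame) {
  A <- frame$axes
  stopifnot(is.matrix(A), all(dim(A) == c(3, 3)))
  g <- crossprod(A)
  if (max(abs(g - diag(3))) > 1e-6) stop("frame axes are not orthonormal")
  if (abs(sum(A[, 1] * cross3(A[, 2], A[, 3])) - 1) > 1e-6)
    stop("frame is not right-handed")
  if (sum(A[, 3] * .DIR_CRANIAL) <= 0) stop("frame z does not point cranially")
  if (sum(A[, 2] * .DIR_ANTERIOR) <= 0) stop("frame y does not point anteriorly")
  invisible(TRUE)
}

# world coordinates of all TRUE voxels (rows)
.mask_coords <- function(mask, spacing, origin) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`)
}

#' Centroid of a binary mask
#'
#' Uniform-weight mean of the voxel-centre coordinates (the structure's
#' centre of gravity under uniform density).
#'
#' @param mask Logical 3D array.
#' @param spacing_mm Voxel spacing (mm).
#' @param origin_mm World coordinate of voxel (0,0,0).
#' @return Numeric length-3 point (mm).
#' @export
mask_centroid <- function(mask, spacing_mm, origin_mm = c(0, 0, 0)) {
  as.numeric(colMeans(.mask_coords(mask, spacing_mm, origin_mm)))
}

#' Volume of a binary mask
#'
#' @inheritParams mask_centroid
#' @return Volume in mm^3 (voxel count times voxel volume).
#' @export
mask_volume <- function(mask, spacing_mm) {
  n <- sum(mask)
  if (n == 0) stop("mask is empty")
  n * prod(spacing_mm)
}

#' Principal (inertia) axes of a mask
#'
#' Eigen-decomposition of the central second-moment (covariance) tensor of
#' the voxel centres. Eigenvectors are returned ordered by decreasing spatial
#' extent, so the third axis -- the direction of smallest extent, i.e. the
#' largest planar moment -- is the candidate craniocaudal (z) axis of a
#' disk-like shape. Near-equal eigenvalues are flagged as degenerate.
#'
#' @inheritParams mask_centroid
#' @param degeneracy_tol Relative eigenvalue gap below which the axes are
#'   flagged degenerate.
#' @return List with `axes` (3x3, columns ordered largest to smallest
#'   extent), `moments` (eigenvalues, mm^2, decreasing) and `degenerate`.
#' @export
principal_axes <- function(mask, spacing_mm, origin_mm = c(0, 0, 0),
                           degeneracy_tol = 0.02) {
  co <- .mask_coords(mask, spacing_mm, origin_mm)
  if (nrow(co) < 4) stop("mask has fewer than 4 voxels; axes are undefined")
  cc <- sweep(co, 2, colMeans(co))
  C <- crossprod(cc) / nrow(cc)
  e <- eigen(C, symmetric = TRUE)
  gaps <- -diff(e$values) / e$values[1]
  list(axes = e$vectors, moments = e$values, degenerate = any(gaps < degeneracy_tol))
}

#' Orient inertia axes into anatomical order
#'
#' Deterministically signs and orders raw inertia axes: the candidate z
#' (smallest extent) is flipped toward scanner-cranial, the candidate y
#' (second-largest extent) toward scanner-anterior, and x is recomputed as
#' `y x z` for right-handedness.
#'
#' @param axes 3x3 matrix from [principal_axes()] (columns by decreasing
#'   extent).
#' @param dirs Scanner directions, see [scanner_directions()].
#' @return 3x3 matrix with columns x, y, z satisfying the [disc_frame()]
#'   invariants.
#' @export
orient_axes <- function(axes, dirs = scanner_directions()) {
  z <- axes[, 3]
  cz <- sum(z * dirs$cranial)
  if (abs(cz) < 0.17)
    stop("disk axis is nearly perpendicular to the cranial direction (~90 degree tilt)")
  if (cz < 0) z <- -z
  y <- axes[, 2]
  cy <- sum(y * dirs$anterior)
  if (abs(cy) < 0.05)
    stop("in-plane axis is nearly perpendicular to the anterior direction")
  if (cy < 0) y <- -y
  # re-orthogonalise y against z (guards tiny numeric drift), then complete
  y <- unit(y - sum(y * z) * z)
  x <- cross3(y, z)
  cbind(x = x, y = y, z = z)
}

#' Patient-corrected sagittal plane
#'
#' Plane through the AF centroids of the most cranial level (T1 analog), the
#' first lumbar level (L1 analog), and the most posteriorly positioned AF
#' among the remaining levels (so a most-posterior AF coinciding with T1 or
#' L1 falls back to the next candidate). The normal is oriented toward
#' scanner-left.
#'
#' @param centroids n x 3 matrix of AF centroids (mm).
#' @param level_index Integer level of each row.
#' @param l1_level Index of the L1-analog level (13 of 17 by default).
#' @param dirs Scanner directions.
#' @return A [plane3()].
#' @export
patient_sagittal_plane <- function(centroids, level_index, l1_level = 13,
                                   dirs = scanner_directions()) {
  stopifnot(nrow(centroids) == length(level_index), nrow(centroids) >= 3)
  t1 <- which.min(level_index)
  l1 <- which(level_index == l1_level)
  if (length(l1) != 1) stop("L1-analog level ", l1_level, " not present")
  others <- setdiff(seq_along(level_index), c(t1, l1))
  if (length(others) == 0) stop("need at least one level besides T1 and L1")
  posterior <- -dirs$anterior
  proj <- as.numeric(centroids[others, , drop = FALSE] %*% posterior)
  post <- others[which.max(proj)]
  a <- centroids[t1, ]; b <- centroids[l1, ]; c <- centroids[post, ]
  u <- b - a; v <- c - a
  ang <- acos(min(1, abs(sum(unit(u) * unit(v))))) * 180 / pi
  if (ang < 0.5)
    stop("defining centroids are collinear within 0.5 degrees; supply a plane manually")
  n <- unit(cross3(u, v))
  if (sum(n * dirs$left) < 0) n <- -n
  plane3(point = a, normal = n)
}

#' Build the corrected disk frame
#'
#' Starts from the oriented inertia axes of the AF mask and rotates the frame
#' about its z axis by the unique angle in (-90, 90] degrees that brings the
#' y axis into the patient sagittal plane (y perpendicular to the plane
#' normal); of the two in-plane directions the anterior-pointing one is kept.
#' The frame origin is the AF centroid.
#'
#' @inheritParams mask_centroid
#' @param af_mask Logical AF mask.
#' @param sagittal A [plane3()], typically from [patient_sagittal_plane()].
#' @param dirs Scanner directions.
#' @return A [disc_frame()].
#' @export
build_disc_frame <- function(af_mask, spacing_mm, origin_mm = c(0, 0, 0),
                             sagittal, dirs = scanner_directions()) {
  pa <- principal_axes(af_mask, spacing_mm, origin_mm)
  ax <- orient_axes(pa$axes, dirs)
  z <- ax[, "z"]; y <- ax[, "y"]
  n <- sagittal$normal
  if (abs(sum(z * n)) > 0.999)
    stop("frame z is parallel to the sagittal normal; y cannot be aligned")
  w <- cross3(z, y)
  theta <- atan2(-sum(y * n), sum(w * n))
  # normalise to (-pi/2, pi/2]: theta and theta +- pi give the same line
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  y2 <- cos(theta) * y + sin(theta) * w
  if (sum(y2 * dirs$anterior) < 0) y2 <- -y2
  y2 <- unit(y2 - sum(y2 * z) * z)
  x2 <- cross3(y2, z)
  disc_frame(origin = mask_centroid(af_mask, spacing_mm, origin_mm),
             axes = cbind(x = x2, y = y2, z = z))
}

# trilinear occupancy of a binary mask at world points (N x 3): interpolates
# the 0/1 voxel field, so the implied surface is the 0.5 isosurface halfway
# between inside and outside voxel centres (sub-voxel, not jagged)
mask_occupancy <- function(mask, spacing_mm, origin_mm, pts) {
  rel <- sweep(sweep(pts, 2, origin_mm), 2, spacing_mm, `/`)
  f <- floor(rel)
  w <- rel - f
  d <- dim(mask)
  occ <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    idx <- f + matrix(c(dx, dy, dz), nrow(f), 3, byrow = TRUE)
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    ok <- idx[, 1] >= 0 & idx[, 1] < d[1] &
          idx[, 2] >= 0 & idx[, 2] < d[2] &
          idx[, 3] >= 0 & idx[, 3] < d[3] & wt > 0
    if (any(ok))
      occ[ok] <- occ[ok] + wt[ok] * mask[idx[ok, , drop = FALSE] + 1]
  }
  occ
}

# membership = occupancy at least 1/2
point_in_mask <- function(mask, spacing_mm, origin_mm, pts) {
  mask_occupancy(mask, spacing_mm, origin_mm, pts) >= 0.5
}

# half-diagonal (mm) of the mask bounding box
.mask_radius <- function(mask, spacing_mm) {
  idx <- which(mask, arr.ind = TRUE)
  span <- (apply(idx, 2, max) - apply(idx, 2, min)) * spacing_mm
  vnorm(span) / 2
}

#' Disk height at the centre of gravity
#'
#' Length of the intersection of the IVD mask with the line through the IVD
#' centroid along the frame z axis. Occupancy is supersampled along the line
#' and the surface crossings (occupancy 0.5) are located by linear
#' interpolation between samples; internal gaps that survive gap closing are
#' included in the chord (last crossing minus first). Because a single chord
#' through a digitized surface inherits the local voxel jag of the two
#' endplates, the estimate is stabilised by averaging a small bundle of
#' parallel chords within about one voxel of the centroid (still the height
#' *at* the centre of gravity, not a footprint-mean height).
#'
#' @inheritParams mask_centroid
#' @param ivd_mask Logical AF-union-NP mask.
#' @param frame A [disc_frame()].
#' @param step_mm Sampling step along the line; default `min(spacing) / 4`.
#' @param bundle_radius_mm Radius of the chord bundle around the centroid;
#'   default 1.5 times the smallest spacing (capped at 2 mm).
#' @return Height in mm.
#' @export
disc_height <- function(ivd_mask, spacing_mm, origin_mm = c(0, 0, 0), frame,
                        step_mm = NULL, bundle_radius_mm = NULL) {
  step <- step_mm %||% (min(spacing_mm) / 4)
  rad <- bundle_radius_mm %||% min(1.5 * min(spacing_mm), 2)
  c0 <- mask_centroid(ivd_mask, spacing_mm, origin_mm)
  R <- .mask_radius(ivd_mask, spacing_mm) + 2
  t <- seq(-R, R, by = step)
  ang <- 2 * pi * (0:7) / 8
  offs <- rbind(c(0, 0), rad * cbind(cos(ang), sin(ang)))
  chords <- apply(offs, 1, function(off) {
    p0 <- c0 + off[1] * frame$axes[, 1] + off[2] * frame$axes[, 2]
    pts <- matrix(p0, length(t), 3, byrow = TRUE) + outer(t, frame$axes[, 3])
    occ <- mask_occupancy(ivd_mask, spacing_mm, origin_mm, pts)
    ins <- which(occ >= 0.5)
    if (length(ins) == 0) return(NA_real_)
    i1 <- ins[1]; i2 <- ins[length(ins)]
    lo <- t[i1]
    if (i1 > 1) lo <- lo - step * (occ[i1] - 0.5) / max(occ[i1] - occ[i1 - 1], 1e-9)
    hi <- t[i2]
    if (i2 < length(t)) hi <- hi + step * (occ[i2] - 0.5) / max(occ[i2] - occ[i2 + 1], 1e-9)
    hi - lo
  })
  if (all(is.na(chords)))
    stop("height line through the centroid misses the mask")
  mean(chords, na.rm = TRUE)
}

#' Transverse cross-sectional area
#'
#' Area of the mask's intersection with the plane through the IVD centroid
#' normal to the frame z axis (the disk's true transverse xy-plane), computed
#' by nearest-voxel membership tests on a regular 2D grid in that plane.
#'
#' @inheritParams disc_height
#' @param cell_mm In-plane sampling cell size (mm).
#' @param margin_mm Extra extent beyond the mask bounding box.
#' @return Area in mm^2 (hit count times cell area).
#' @export
cross_sectional_area <- function(ivd_mask, spacing_mm, origin_mm = c(0, 0, 0),
                                 frame, cell_mm = 0.2, margin_mm = 2) {
  c0 <- mask_centroid(ivd_mask, spacing_mm, origin_mm)
  R <- .mask_radius(ivd_mask, spacing_mm) + margin_mm
  s <- seq(-R, R, by = cell_mm)
  g <- as.matrix(expand.grid(u = s, v = s))
  pts <- matrix(c0, nrow(g), 3, byrow = TRUE) +
    g[, 1] %o% frame$axes[, 1] + g[, 2] %o% frame$axes[, 2]
  hits <- point_in_mask(ivd_mask, spacing_mm, origin_mm, pts)
  if (!any(hits)) stop("transverse plane through the centroid misses the mask")
  sum(hits) * cell_mm^2
}

#' Disk slenderness
#'
#' Height divided by the square root of the transverse cross-sectional area;
#' a unitless proxy for the disk's mechanical stability.
#'
#' @param H Height (mm), positive.
#' @param A Cross-sectional area (mm^2), positive.
#' @return `H / sqrt(A)`.
#' @export
slenderness <- function(H, A) {
  if (any(H <= 0) || any(A <= 0)) stop("height and area must be positive")
  H / sqrt(A)
}

#' Nucleus centroid offset
#'
#' Offset of the NP centre of gravity relative to the centre of gravity of
#' the whole IVD, expressed in the disk frame. Components are reported along
#' the anatomical directions: positive `dx` = leftward (the negative frame x,
#' which points right), positive `dy` = anterior, positive `dz` = cranial.
#'
#' @inheritParams disc_height
#' @param np_mask Logical NP mask.
#' @return Named numeric `c(dx, dy, dz)` in mm.
#' @export
nucleus_offset <- function(np_mask, ivd_mask, spacing_mm, origin_mm = c(0, 0, 0),
                           frame) {
  d <- mask_centroid(np_mask, spacing_mm, origin_mm) -
       mask_centroid(ivd_mask, spacing_mm, origin_mm)
  c(dx = -sum(d * frame$axes[, 1]),
    dy = sum(d * frame$axes[, 2]),
    dz = sum(d * frame$axes[, 3]))
}

#' Measure one disk
#'
#' Runs the full per-disk measurement chain on an AF/NP mask pair: builds the
#' corrected frame from the AF, then extracts height, cross-sectional area,
#' slenderness, volumes, the NP:IVD ratio and the nucleus offset. `V_IVD` is
#' the sum of the AF and NP volumes by construction.
#'
#' @param dm A `disc_masks` pair from [extract_disc_masks()].
#' @param sagittal A [plane3()] for the rotation correction; `NULL` uses the
#'   scanner mid-sagittal plane through the AF centroid (appropriate for
#'   single-disk volumes in scanner-aligned pose).
#' @param line_step_mm,csa_cell_mm,csa_margin_mm Sampling controls, see
#'   [disc_height()] and [cross_sectional_area()].
#' @return One-row data frame with columns `level_index`, `H_mm`, `A_mm2`,
#'   `S`, `V_AF_mm3`, `V_NP_mm3`, `V_IVD_mm3`, `np_ratio`, `off_x_mm`,
#'   `off_y_mm`, `off_z_mm`.
#' @export
measure_disc <- function(dm, sagittal = NULL, line_step_mm = NULL,
                         csa_cell_mm = 0.2, csa_margin_mm = 2) {
  stopifnot(inherits(dm, "disc_masks"))
  if (!any(dm$af) || !any(dm$np)) stop("AF and NP masks must both be nonempty")
  if (any(dm$af & dm$np)) stop("AF and NP masks overlap; input labels are invalid")
  sp <- dm$spacing; or <- dm$origin
  if (is.null(sagittal))
    sagittal <- plane3(point = mask_centroid(dm$af, sp, or), normal = .DIR_LEFT)
  frame <- build_disc_frame(dm$af, sp, or, sagittal)
  ivd <- dm$af | dm$np
  H <- disc_height(ivd, sp, or, frame, step_mm = line_step_mm)
  A <- cross_sectional_area(ivd, sp, or, frame, cell_mm = csa_cell_mm,
                            margin_mm = csa_margin_mm)
  V_AF <- mask_volume(dm$af, sp)
  V_NP <- mask_volume(dm$np, sp)
  off <- nucleus_offset(dm$np, ivd, sp, or, frame)
  data.frame(level_index = dm$level_index, H_mm = H, A_mm2 = A,
             S = slenderness(H, A), V_AF_mm3 = V_AF, V_NP_mm3 = V_NP,
             V_IVD_mm3 = V_AF + V_NP, np_ratio = V_NP / (V_AF + V_NP),
             off_x_mm = off[["dx"]], off_y_mm = off[["dy"]], off_z_mm = off[["dz"]])
}
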