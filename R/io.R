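# Labeled-volume I/O, label-schema resolution, gap closing, exclusion filter.

#' Labeled volume
#'
#' A 3D integer label grid with voxel spacing and a world-space origin.
#' World coordinates are NIfTI RAS millimetres (+x right, +y anterior,
#' +z superior); the coordinate of voxel index `(i,j,k)` (0-based) is
#' `origin + c(i,j,k) * spacing` (voxel-centre convention).
#'
#' @param labels 3D array of non-negative integer labels.
#' @param spacing_mm Positive voxel spacing (mm) per axis.
#' @param origin_mm World coordinate (mm) of the centre of voxel (0,0,0).
#' @param axes Anatomical direction each array axis increases toward
#'   (canonical volumes are `c("R","A","S")`).
#' @return A `labeled_volume` object.
#' @export
labeled_volume <- function(labels, spacing_mm, origin_mm = c(0, 0, 0),
                           axes = c("R", "A", "S")) {
  stopifnot(length(dim(labels)) == 3, length(spacing_mm) == 3,
            all(spacing_mm > 0), length(origin_mm) == 3)
  if (!is.integer(labels)) {
    if (any(labels != round(labels)) || any(labels < 0))
      stop("labels must be non-negative integers")
    storage.mode(labels) <- "integer"
  }
  structure(list(labels = labels, spacing = as.numeric(spacing_mm),
                 origin = as.numeric(origin_mm), axes = axes),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s voxels, spacing %s mm, %d nonzero labels\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              length(setdiff(unique(as.integer(x$labels)), 0L))))
  invisible(x)
}

#' Write a labeled volume as NIfTI
#'
#' @param vol A [labeled_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_labeled_volume <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  img <- RNifti::asNifti(vol$labels)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a labeled volume from NIfTI
#'
#' Accepts 3D integer label maps with an axis-aligned (non-oblique) affine.
#' Axes with negative direction are flipped so the returned volume is in
#' canonical RAS order with positive spacing. Labels present in the file but
#' absent from `schema` trigger a warning and are left in place (they are
#' ignored at mask extraction).
#'
#' @param path NIfTI file.
#' @param schema Optional label schema (see [default_label_schema()]) used to
#'   report unknown labels.
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(path, schema = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3)
    stop("expected a 3D label volume, got ", length(dim(arr)), " dimensions")
  if (any(arr != round(arr)) || any(arr < 0))
    stop("volume does not contain non-negative integer labels")
  arr <- array(as.integer(arr), dim(arr))  # strip image attributes
  xf <- RNifti::xform(img)
  A <- xf[1:3, 1:3]
  origin <- xf[1:3, 4]
  # require axis-aligned affine: one dominant entry per column
  perm <- apply(abs(A), 2, which.max)
  if (any(sort(perm) != 1:3))
    stop("affine is not axis-aligned; oblique volumes are not supported")
  offdiag <- A; for (j in 1:3) offdiag[perm[j], j] <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(A))))
    stop("affine is not axis-aligned; oblique volumes are not supported")
  if (any(perm != 1:3)) {
    arr <- aperm(arr, order(perm))
    A <- A[, order(perm)]
    # origin refers to index (0,0,0) which is unchanged by aperm
  }
  spacing <- diag(A)
  for (ax in 1:3) {
    if (spacing[ax] < 0) {
      idx <- rev(seq_len(dim(arr)[ax]))
      arr <- switch(ax, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
                    arr[, , idx, drop = FALSE])
      origin[ax] <- origin[ax] + spacing[ax] * (dim(arr)[ax] - 1)
      spacing[ax] <- -spacing[ax]
    }
  }
  vol <- labeled_volume(arr, spacing, origin)
  if (!is.null(schema)) {
    present <- setdiff(unique(as.integer(arr)), 0L)
    unknown <- setdiff(present, schema$label)
    if (length(unknown) > 0)
      warning("labels not in schema (ignored): ", paste(sort(unknown), collapse = ", "))
  }
  vol
}

#' Label schema
#'
#' Maps each (level, structure) pair to a label id. The default schema labels
#' the AF of level k as `2k - 1` and the NP as `2k`.
#'
#' @param n_levels Number of disk levels.
#' @return Data frame with columns `level_index`, `structure` (`"AF"`/`"NP"`)
#'   and `label`.
#' @export
default_label_schema <- function(n_levels = 17) {
  data.frame(
    level_index = rep(seq_len(n_levels), each = 2),
    structure = rep(c("AF", "NP"), n_levels),
    label = as.integer(seq_len(2 * n_levels))
  )
}

#' @rdname default_label_schema
#' @param schema A label schema data frame.
#' @param path CSV path.
#' @export
write_label_schema <- function(schema, path) {
  utils::write.csv(schema, path, row.names = FALSE)
  invisible(path)
}

#' @rdname default_label_schema
#' @export
read_label_schema <- function(path) {
  schema <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_label_schema(schema)
  schema
}

validate_label_schema <- function(schema) {
  stopifnot(all(c("level_index", "structure", "label") %in% names(schema)))
  if (anyDuplicated(schema$label) || any(schema$label == 0))
    stop("label ids must be unique and nonzero")
  byl <- split(schema$structure, schema$level_index)
  if (!all(vapply(byl, function(s) all(c("AF", "NP") %in% s), logical(1))))
    stop("every level must have both an AF and an NP label")
  invisible(TRUE)
}

#' Extract per-disk AF/NP mask pairs
#'
#' Resolves the schema into one binary mask pair per level. Levels missing
#' either structure in the volume are skipped with a message. Overlap between
#' AF and NP labels is impossible by construction (one label per voxel).
#'
#' @param vol A [labeled_volume()].
#' @param schema A label schema.
#' @return List of `disc_masks` objects, each with `level_index`, logical
#'   arrays `af` and `np`, plus the grid `spacing` and `origin`.
#' @export
extract_disc_masks <- function(vol, schema) {
  stopifnot(inherits(vol, "labeled_volume"))
  validate_label_schema(schema)
  present <- setdiff(unique(as.integer(vol$labels)), 0L)
  out <- list()
  for (lvl in sort(unique(schema$level_index))) {
    rows <- schema[schema$level_index == lvl, ]
    af_id <- rows$label[rows$structure == "AF"]
    np_id <- rows$label[rows$structure == "NP"]
    if (!(af_id %in% present) || !(np_id %in% present)) {
      message(sprintf("level %d skipped: missing %s", lvl,
                      paste(c("AF", "NP")[!c(af_id, np_id) %in% present], collapse = "+")))
      next
    }
    out[[length(out) + 1]] <- structure(list(
      level_index = lvl,
      af = vol$labels == af_id,
      np = vol$labels == np_id,
      spacing = vol$spacing, origin = vol$origin
    ), class = "disc_masks")
  }
  if (length(out) == 0) stop("no level could be resolved from the schema")
  out
}

# structuring element: integer offsets within a metric ball of radius r (mm)
.ball_offsets <- function(radius_mm, spacing) {
  reach <- pmax(floor(radius_mm / spacing), 0)
  off <- as.matrix(expand.grid(i = -reach[1]:reach[1], j = -reach[2]:reach[2],
                               k = -reach[3]:reach[3]))
  d2 <- (off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 + (off[, 3] * spacing[3])^2
  off[d2 <= radius_mm^2 + 1e-12, , drop = FALSE]
}

.shift_or <- function(acc, mask, off) {
  d <- dim(mask)
  src <- lapply(1:3, function(ax) {
    s <- seq_len(d[ax]) - off[ax]
    pmin(pmax(s, 1L), d[ax])
  })
  # only keep in-range contributions
  ok <- lapply(1:3, function(ax) {
    s <- seq_len(d[ax]) - off[ax]
    s >= 1L & s <= d[ax]
  })
  sh <- mask[src[[1]], src[[2]], src[[3]], drop = FALSE]
  sh[!ok[[1]], , ] <- FALSE
  sh[, !ok[[2]], ] <- FALSE
  sh[, , !ok[[3]]] <- FALSE
  acc | sh
}

.dilate <- function(mask, offsets) {
  acc <- array(FALSE, dim(mask))
  for (r in seq_len(nrow(offsets))) acc <- .shift_or(acc, mask, offsets[r, ])
  acc
}

.erode <- function(mask, offsets) {
  # erosion = complement of dilation of the complement (reflected element;
  # the metric ball is symmetric)
  !.dilate(!mask, offsets)
}

#' Close small gaps in a binary mask
#'
#' Morphological closing with a metric ball of radius `max_gap_mm / 2` in
#' millimetre space, so the structuring element adapts to anisotropic voxels.
#' The mask is padded before closing, which guarantees the result is a
#' superset of the input; gaps narrower than `max_gap_mm` along any grid axis
#' do not survive. This mirrors the "wrap" refinement used on segmentation
#' models (gap filling only; surface smoothing is out of scope).
#'
#' @param mask Logical 3D array.
#' @param spacing_mm Voxel spacing (mm).
#' @param max_gap_mm Largest gap width (mm) to fill; `0` is the identity.
#' @return Logical array of the same dimensions.
#' @export
close_small_gaps <- function(mask, spacing_mm, max_gap_mm = 1.0) {
  stopifnot(length(dim(mask)) == 3, max_gap_mm >= 0)
  if (max_gap_mm == 0) return(mask)
  offsets <- .ball_offsets(max_gap_mm / 2, spacing_mm)
  if (nrow(offsets) <= 1) return(mask)
  pad <- unname(apply(abs(offsets), 2, max))
  d <- dim(mask)
  padded <- array(FALSE, d + 2 * pad)
  padded[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])] <- mask
  closed <- .erode(.dilate(padded, offsets), offsets)
  out <- closed[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])]
  out | mask
}

#' Apply cohort exclusion filters
#'
#' @param manifest A cohort manifest (see [generate_cohort_manifest()] /
#'   [read_cohort_manifest()]).
#' @return List with `included` (rows flagged `"none"`) and `report`
#'   (named counts per exclusion reason). `nrow(included) + sum(report)`
#'   always equals `nrow(manifest)`.
#' @export
apply_exclusion_filters <- function(manifest) {
  stopifnot(all(c("scan_id", "exclusion_flag") %in% names(manifest)))
  flag <- factor(as.character(manifest$exclusion_flag), levels = EXCLUSION_FLAGS)
  if (anyNA(flag)) stop("manifest contains exclusion flags outside the known set")
  included <- manifest[flag == "none", , drop = FALSE]
  report <- table(flag[flag != "none"])
  report <- stats::setNames(as.integer(report), names(report))
  report <- report[setdiff(EXCLUSION_FLAGS, "none")]
  names(report) <- setdiff(EXCLUSION_FLAGS, "none")
  list(included = included, report = report)
}

#' @rdname apply_exclusion_filters
#' @param path CSV path with header `scan_id,age_years,sex,exclusion_flag`.
#' @export
read_cohort_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "age_years", "sex", "exclusion_flag")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(man$scan_id)) stop("scan_id values must be unique")
  man$exclusion_flag <- factor(man$exclusion_flag, levels = EXCLUSION_FLAGS)
  if (anyNA(man$exclusion_flag)) stop("unknown exclusion flag in manifest")
  class(man) <- c("cohort_manifest", "data.frame")
  man
}

#' @rdname apply_exclusion_filters
#' @param manifest A cohort manifest to write.
#' @export
write_cohort_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Cohort inventory arithmetic
#'
#' Counts the disks and segmented structures a cohort contributes: each
#' included scan carries `n_levels` disks and two structures (AF and NP) per
#' disk.
#'
#' @param manifest A cohort manifest.
#' @param n_levels Disk levels per scan.
#' @return List with `n_scans`, `n_disks`, `n_structures`.
#' @export
cohort_inventory <- function(manifest, n_levels = 17) {
  inc <- apply_exclusion_filters(manifest)$included
  n <- nrow(inc)
  list(n_scans = as.integer(n), n_disks = as.integer(n * n_levels),
       n_structures = as.integer(2 * n * n_levels))
}
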