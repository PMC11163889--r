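#' Level groups and age groups
#'
#' Spinal level groups follow the SRS convention: upper-thoracic (T1--T4),
#' mid-thoracic (T5--T8), low-thoracic (T9--T12) and lumbar (L1--L5). With the
#' default 17 craniocaudal disk levels per scan these map to index ranges
#' 1--4, 5--8, 9--12 and 13--17.
#'
#' @format Character vector of the four level-group names.
#' @export
LEVEL_GROUPS <- c("upper_thoracic", "mid_thoracic", "low_thoracic", "lumbar")

#' @rdname LEVEL_GROUPS
#' @export
AGE_GROUPS <- c("infantile", "juvenile", "adolescent")

#' Map a disk level index to its level group
#'
#' @param level_index Integer vector of craniocaudal disk indices (1-based).
#' @param n_levels Number of disk levels per scan (default 17).
#' @return Factor with levels [LEVEL_GROUPS].
#' @export
level_group_of <- function(level_index, n_levels = 17) {
  stopifnot(all(level_index >= 1), all(level_index <= n_levels))
  # index ranges mirror T1-L5 for the default 17 levels; scale for other counts
  br <- round(c(4, 8, 12) / 17 * n_levels)
  g <- ifelse(level_index <= br[1], "upper_thoracic",
       ifelse(level_index <= br[2], "mid_thoracic",
       ifelse(level_index <= br[3], "low_thoracic", "lumbar")))
  factor(g, levels = LEVEL_GROUPS)
}

#' Map age in years to the SRS age group
#'
#' Groups are defined on whole years (floor of age): infantile 0--3,
#' juvenile 4--10, adolescent 11--18.
#'
#' @param age_years Numeric vector of ages in years.
#' @return Factor with levels [AGE_GROUPS].
#' @export
age_group_of <- function(age_years) {
  if (any(age_years < 0 | age_years > 18)) stop("age_years must lie in [0, 18]")
  a <- floor(age_years)
  g <- ifelse(a <= 3, "infantile", ifelse(a <= 10, "juvenile", "adolescent"))
  factor(g, levels = AGE_GROUPS)
}

#' Default growth-curve table for the spine-phantom generator
#'
#' Piecewise-linear anchor curves over age 0--18 years, per level group and
#' sex, for disk height (mm), transverse cross-sectional area (mm^2), the
#' NP:IVD volume ratio (fraction), and the anterior-posterior nucleus offset
#' (mm, + = anterior). The anchors encode the growth pattern the phantom
#' emulates:
#'
#' * height grows mainly in the low-thoracic (4 to 7 mm) and lumbar
#'   (5 to 10 mm) spine during the first 10 years and is flat afterwards;
#'   upper/mid-thoracic height plateaus near 5 mm;
#' * cross-sectional area increases throughout growth, with birth-to-18
#'   multiplication factors of 4.2 (M) / 2.5 (F) upper-thoracic and
#'   5.2 (M) / 3.9 (F) lumbar;
#' * mid-thoracic CSA anchors are derived as (height / slenderness)^2 from a
#'   slenderness trajectory whose values at integer ages 9--13 average 0.270
#'   for males and 0.230 for females;
#' * the NP:IVD ratio stays at 0.10--0.12 in the upper/mid-thoracic spine and
#'   rises to about 0.19-0.20 low-thoracic and 0.23-0.25 lumbar by age 18;
#' * the nucleus drifts posteriorly in the mid-thoracic spine and anteriorly
#'   in the lumbar spine with age, and stays centred left-right and
#'   cranio-caudally.
#'
#' @return An object of class `growth_table`: a nested list keyed by level
#'   group then sex (`"M"`/`"F"`), each leaf holding anchor data frames
#'   `height_mm`, `csa_mm2`, `np_ratio`, `np_offset_y_mm` with columns
#'   `age` and `value`.
#' @export
default_growth_table <- function() {
  anch <- function(age, value) data.frame(age = age, value = value)

  # mid-thoracic CSA derived from height and slenderness trajectories
  mid_ages <- c(0, 3, 5, 9, 10, 11, 12, 13, 18)
  mid_h_M <- piecewise_linear(c(0, 5, 10, 18), c(3.8, 4.8, 5.3, 5.3), mid_ages)
  mid_h_F <- piecewise_linear(c(0, 5, 10, 18), c(3.6, 4.6, 5.0, 5.0), mid_ages)
  mid_s_M <- c(0.380, 0.272, 0.268, 0.274, 0.272, 0.270, 0.268, 0.266, 0.256)
  mid_s_F <- c(0.285, 0.243, 0.246, 0.234, 0.232, 0.230, 0.228, 0.226, 0.218)

  tab <- list(
    upper_thoracic = list(
      M = list(height_mm = anch(c(0, 10, 18), c(3.6, 4.9, 4.9)),
               csa_mm2 = anch(c(0, 4, 18), c(470 / 4.2, 310, 470)),
               np_ratio = anch(c(0, 18), c(0.10, 0.12)),
               np_offset_y_mm = anch(c(0, 18), c(0, 0))),
      F = list(height_mm = anch(c(0, 10, 18), c(3.4, 4.7, 4.7)),
               csa_mm2 = anch(c(0, 4, 18), c(420 / 2.5, 300, 420)),
               np_ratio = anch(c(0, 18), c(0.10, 0.12)),
               np_offset_y_mm = anch(c(0, 18), c(0, 0)))
    ),
    mid_thoracic = list(
      M = list(height_mm = anch(c(0, 5, 10, 18), c(3.8, 4.8, 5.3, 5.3)),
               csa_mm2 = anch(mid_ages, (mid_h_M / mid_s_M)^2),
               np_ratio = anch(c(0, 18), c(0.10, 0.12)),
               np_offset_y_mm = anch(c(0, 3, 18), c(0, -0.1, -1.0))),
      F = list(height_mm = anch(c(0, 5, 10, 18), c(3.6, 4.6, 5.0, 5.0)),
               csa_mm2 = anch(mid_ages, (mid_h_F / mid_s_F)^2),
               np_ratio = anch(c(0, 18), c(0.10, 0.12)),
               np_offset_y_mm = anch(c(0, 3, 18), c(0, -0.1, -1.0)))
    ),
    low_thoracic = list(
      M = list(height_mm = anch(c(0, 10, 18), c(4.2, 7.2, 7.2)),
               csa_mm2 = anch(c(0, 4, 18), c(900 / 4.8, 450, 900)),
               np_ratio = anch(c(0, 18), c(0.14, 0.19)),
               np_offset_y_mm = anch(c(0, 18), c(0, 0.5))),
      F = list(height_mm = anch(c(0, 10, 18), c(4.0, 7.0, 7.0)),
               csa_mm2 = anch(c(0, 4, 18), c(750 / 3.6, 400, 750)),
               np_ratio = anch(c(0, 18), c(0.12, 0.20)),
               np_offset_y_mm = anch(c(0, 18), c(0, 0.5)))
    ),
    lumbar = list(
      M = list(height_mm = anch(c(0, 10, 18), c(5, 10, 10)),
               csa_mm2 = anch(c(0, 4, 18), c(2030 / 5.2, 950, 2030)),
               np_ratio = anch(c(0, 18), c(0.18, 0.23)),
               np_offset_y_mm = anch(c(0, 3, 18), c(0, 0.2, 1.5))),
      F = list(height_mm = anch(c(0, 10, 18), c(5, 10, 10)),
               csa_mm2 = anch(c(0, 4, 18), c(1500 / 3.9, 820, 1500)),
               np_ratio = anch(c(0, 18), c(0.17, 0.25)),
               np_offset_y_mm = anch(c(0, 3, 18), c(0, 0.2, 1.5)))
    )
  )
  structure(tab, class = "growth_table")
}

#' Validate a growth table against its invariants
#'
#' Checks that every anchor list is age-sorted within [0, 18], that all
#' height/CSA anchors are strictly positive, and that np_ratio lies in
#' (0, 0.5) everywhere.
#'
#' @param table A `growth_table`.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_growth_table <- function(table) {
  stopifnot(inherits(table, "growth_table"))
  for (grp in names(table)) for (sx in names(table[[grp]])) {
    curves <- table[[grp]][[sx]]
    for (nm in c("height_mm", "csa_mm2", "np_ratio", "np_offset_y_mm")) {
      a <- curves[[nm]]
      if (is.null(a)) stop(sprintf("missing curve %s for (%s, %s)", nm, grp, sx))
      if (is.unsorted(a$age) || any(a$age < 0) || any(a$age > 18))
        stop(sprintf("anchor ages for %s (%s, %s) must be sorted in [0, 18]", nm, grp, sx))
      if (nm != "np_offset_y_mm" && any(a$value <= 0))
        stop(sprintf("%s anchors for (%s, %s) must be strictly positive", nm, grp, sx))
      if (nm == "np_ratio" && any(a$value >= 0.5))
        stop(sprintf("np_ratio anchors for (%s, %s) must lie in (0, 0.5)", grp, sx))
    }
  }
  invisible(TRUE)
}

#' Interpolate growth curves at an age
#'
#' @param table A `growth_table`.
#' @param level_group One of [LEVEL_GROUPS].
#' @param sex `"M"` or `"F"`.
#' @param age Age in years, in [0, 18].
#' @return A list with `height_mm`, `csa_mm2`, `np_ratio`, `np_offset_y_mm`
#'   interpolated piecewise-linearly at `age`.
#' @export
growth_at <- function(table, level_group, sex, age) {
  stopifnot(inherits(table, "growth_table"))
  level_group <- match.arg(as.character(level_group), LEVEL_GROUPS)
  sex <- match.arg(as.character(sex), c("M", "F"))
  if (any(age < 0 | age > 18)) stop("age must lie in [0, 18]")
  curves <- table[[level_group]][[sex]]
  lapply(curves, function(a) piecewise_linear(a$age, a$value, age))
}
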