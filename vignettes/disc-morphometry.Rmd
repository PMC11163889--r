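---
title: "Disk morphometry from labeled volumes: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disk morphometry from labeled volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discmorph)
```

`discmorph` measures intervertebral disks (IVD) from labeled segmentation
volumes in which every disk level contributes two integer labels: the
annulus fibrosus (AF) shell and the nucleus pulposus (NP) core. This
vignette explains the measurement model, the phantom used to validate it,
the numerical conventions, and the places where the design was genuinely
open and a choice had to be made.

## The measurement model

All geometry lives in scanner RAS millimetre space (+x right, +y anterior,
+z superior); a voxel's coordinate is the affine image of its index
(voxel-centre convention, 0-based indices). The per-disk chain is:

1. **Gap closing.** Morphological closing with a metric ball of radius
   `max_gap_mm / 2` (default `max_gap_mm` = 1 mm) in millimetre space, so
   the structuring element adapts to anisotropic voxels. This mirrors the
   "wrap"-style refinement used on segmentation models: gaps narrower than
   1 mm do not survive, and the operation is extensive (output contains the
   input), monotone and idempotent. Only gap filling is reproduced; surface
   smoothing is not, because every downstream measure is integral- or
   centroid-based and insensitive to voxel-scale surface texture.
2. **Inertia frame.** The AF mask's central second-moment tensor (the
   covariance of its voxel centres) is eigen-decomposed. For a disk-like
   shape the eigenvector of smallest spatial extent is the craniocaudal
   candidate; the largest in-plane extent is left–right. We use the
   covariance tensor rather than the physics inertia tensor: the
   eigenvectors are identical and the ordering convention is explicit.
   Near-equal eigenvalues (relative gap below 2 %) raise a degeneracy flag;
   masks with fewer than 4 voxels are rejected.
3. **Anatomical signing.** The candidate z is flipped toward
   scanner-cranial, the candidate y toward scanner-anterior, and x is
   recomputed as `y × z`. A disk tilted ~90° from axial (|z·cranial| <
   0.17) is an error, not a guess. Note a consequence of right-handedness:
   with y anterior and z cranial, `x = y × z` necessarily points to the
   patient's *right*; nucleus offsets are therefore reported with the x
   component sign-flipped so that positive `dx` means leftward, matching
   the (left, anterior, cranial) reporting convention.
4. **Sagittal rotation correction.** Patients lie in the scanner slightly
   rotated. The patient sagittal plane is defined by three AF centroids:
   the most cranial level (T1 analog), the first lumbar level, and the most
   posteriorly positioned AF among the remaining levels — so if the most
   posterior AF *is* T1 or L1, the next candidate is used (three distinct
   points are required; the tie is not otherwise addressable). Each disk
   frame is then rotated about its own z by the unique angle in (−90°, 90°]
   that brings y into the plane, keeping the anterior-pointing solution.
   Three near-collinear defining centroids (within 0.5°) are an error that
   asks for a manually supplied plane.
5. **Morphometry.** Height `H` is the chord of the AF∪NP mask along frame z
   through the IVD centroid; cross-sectional area `A` is the mask's
   intersection with the transverse plane through the centroid; slenderness
   `S = H/√A`; volumes are voxel counts times voxel volume, with
   `V_IVD = V_AF + V_NP` exact by construction; the nucleus offset is the
   difference between the NP centroid and the whole-IVD centroid projected
   on the frame axes. Frames are built from the **AF** alone (it is the
   load-bearing ring and the structure segmented most reliably), while
   height, area and the offset reference use the **whole IVD**.

### Sub-voxel sampling conventions

Binary masks are sampled through trilinear interpolation of the 0/1 voxel
field; a point is "inside" when its occupancy reaches 0.5. The implied
surface is the 0.5-isosurface halfway between inside and outside voxel
centres — sub-voxel, instead of the jagged staircase a nearest-voxel lookup
sees.

* **Height** supersamples occupancy along the chord (step = min spacing / 4)
  and locates the two 0.5-crossings by linear interpolation between samples.
  A *single* chord still inherits the local digitization jag of the two
  endplate surfaces (up to ±0.2 mm at 0.5 mm voxels), so the reported height
  averages a bundle of nine parallel chords within about one voxel
  (1.5 × min spacing, capped at 2 mm) of the centroid. This is still the
  height *at* the centre of gravity — the bundle radius is far below the
  scale on which disk height varies — not the footprint-mean height variant,
  which exists in the literature but is not the default here. Internal gaps
  that survive gap closing remain part of the chord (first to last
  crossing).
* **Area** counts 0.2 mm cells of a regular grid in the transverse plane
  (bounding box + 2 mm margin) whose occupancy reaches 0.5. Cell size and
  line step are chosen so discretization error is far below the 3–4 mm
  slice-thickness uncertainty that dominates real acquisitions of this kind.

## The spine phantom

No clinical images ship with the package; instead a generator produces
labeled spine volumes whose ground truth is known exactly, which is what
makes accuracy claims testable.

**Disk shape.** Each IVD envelope is a superellipsoid
`(|x/a|^n + |y/b|^n) + |2z/H|^m ≤ 1` with in-plane exponent `n = 2.5` and
aspect `b/a = 0.7` (a kidney-ish footprint; the source data constrain only
the area, not the outline) and craniocaudal exponent `m = 8` — gently
rounded endplate caps. The rounded caps were a deliberate choice over a flat
cylinder: a flat cap makes the voxel-centre centroid phase-locked to the
grid (error uniform ±spacing/2 along z however fine the in-plane grid),
which is both anatomically implausible and numerically hostile; with `m = 8`
centroids are sub-voxel stable while the mid-height cross-section (area
`A = c(n)·a·b`), the centroid chord (exactly `H`) and hence slenderness stay
analytic. The envelope volume is `k(n,m)·A·H` with
`k = Γ(1+1/m)Γ(1+2/n)/Γ(1+1/m+2/n)` (≈ 0.904 at the defaults). Flat caps
(`z_exponent = Inf`) remain available and are used for the elliptic-cylinder
analytic oracles in the tests. The NP is an ellipsoid with the same in-plane
aspect, craniocaudal semi-axis `0.35·H`, sized so `V_NP/V_IVD` matches the
growth curve exactly, and offset anteriorly/posteriorly per the curve.

**Growth curves.** `default_growth_table()` stores piecewise-linear anchors
over age 0–18 per level group and sex. The anchors encode: low-thoracic
height 4→7 mm and lumbar 5→10 mm with heights flat after age 10;
upper/mid-thoracic plateaus near 5 mm; CSA rising throughout growth with
birth-to-18 factors 4.2 (M) / 2.5 (F) upper-thoracic and 5.2 (M) / 3.9 (F)
lumbar; NP:IVD ratio stable at 0.10–0.12 upper/mid-thoracic and rising to
0.19–0.25 caudally; and an age-increasing anterior (lumbar) / posterior
(mid-thoracic) nucleus drift. Mid-thoracic CSA anchors are *derived* as
`(height/slenderness)²` from a slenderness trajectory whose integer-age
values over 9–13 average exactly 0.270 (M) and 0.230 (F): the generator is
calibrated so that the pipeline's ability to *recover* those values is a
meaningful end-to-end test. Mid- and low-thoracic CSA factors are not
separately constrained by the anchors above, so values between the
upper-thoracic and lumbar factors were fixed once (4.29/3.30 and 4.8/3.6).
One consequence is worth stating plainly: with near-equal heights, a male
slenderness of 0.27 against a female 0.23 forces male mid-thoracic CSA
*below* female CSA — the slenderness anchors and a global "male disks are
larger" ordering cannot both hold, and the slenderness anchors won.

**Noise model.** Per-disk jitter is multiplicative log-normal with
`sdlog = sqrt(log(1 + cv²))` and `meanlog = −sdlog²/2`, so the multiplier
has mean exactly 1 and coefficient of variation exactly `jitter_sd`
(default 0.03 for cohort phantoms), and all sizes stay positive. Jitter
draws that would push the NP outside the AF envelope are clamped with a
warning.

**Scene.** Disks are stacked along a fixed two-arc sagittal profile
(thoracic kyphosis 30°, lumbar lordosis 40°, all ages): the curvature's only
job is to exercise the sagittal-plane construction and the per-disk rotation
correction, and published angles for every age do not exist. 17 levels per
scan mirror the counting arithmetic of the emulated cohort (126 scans ×
17 disks = 2142). The voxel grid origin gets a seeded uniform sub-voxel
offset — a patient's position relative to the scanner lattice is arbitrary —
so digitization phase is random rather than a fixed bias; recovery sweeps
additionally give each disk a small random pose (±10°), as real scans have.
The default spacing (3.5 × 0.5 × 0.5 mm, slices stacked left–right) emulates
a sagittal acquisition; validation runs use 0.5 mm isotropic grids.

**What the phantom does not emulate** — and therefore what passing tests do
*not* show about clinical data: no MR intensities or segmentation ambiguity
(labels are perfect by construction), no vertebral bodies or endplates, no
disk degeneration, no shape irregularity beyond the superellipsoid family,
and no within-subject correlation structure beyond shared growth-curve
parameters. Accuracy statements are about the *measurement* chain given
correct masks, not about segmentation quality.

## Statistics layer

* **Stratification** assigns level groups by index ranges mirroring T1–L5
  (1–4, 5–8, 9–12, 13–17 of 17) and SRS age groups on `floor(age)` —
  the groups are stated in whole years, so age 10.5 is juvenile.
* **LOESS** (`loess_fit()`) is Cleveland's tricube local polynomial via
  `stats::loess` with direct surface evaluation, span 0.75 and degree 1 by
  default; local-linear fits reproduce straight lines exactly, which the
  tests exploit as an oracle. Growth curves are fitted to per-subject
  level-group means (one dot per subject and group), the convention used in
  cross-sectional growth plots.
* **Percent change** is reported as `100 · fit(18)/fit(0)` — "the increase
  was 460 %" means the final value is 4.6× the initial one. The alternative
  reading (`(final−initial)/initial`) differs by exactly 100 points, so the
  convention is documented and pinned by a test ("4 to 7 mm" ⇔ 175 %).
* **Sex comparison** uses Welch's unequal-variance t test: equal variances
  between boys' and girls' disks cannot be assumed and the cost of Welch
  under equality is negligible.
* **Trend tests** are OLS of the outcome on age (optionally sex-adjusted).
  The emulated protocol names "simple logistic regression" for continuous
  morphometric outcomes, which is not a defined procedure; rather than
  invent a dichotomization, the package fits linear trends and says so.
* **ICC** is the two-way random-effects, absolute-agreement, single-measure
  coefficient computed from the ANOVA mean squares, with F-based 95 %
  confidence bounds (McGraw–Wong ICC(A,1)) — the standard model for intra-
  and inter-operator segmentation reliability when raters are a random
  sample. Degenerate inputs are explicit errors: fewer than 2 items or
  raters, or zero total variance. Perfect agreement returns ICC 1 with a
  point interval.

## Problem sizes and tolerances used in validation

The shipped tests digitize analytic shapes (elliptic cylinders, ellipsoids,
hemispheres) at 0.25–1 mm and require closed-form agreement within 1–2 %;
rotation-invariance sweeps run six poses up to 30° on 0.5 mm grids with a
2 % budget for lengths/areas/volumes and 0.2 mm for offset components;
ground-truth recovery regresses measured on true values over 100 jittered
disks spanning all ages, levels and both sexes (slope within 1 ± 0.03,
R² > 0.99); and the calibrated-anchor recovery measures 20 disks per age
cell. Cohort-pipeline tests use scaled-down scans (6 levels, 1 mm voxels) —
the pipeline is size-agnostic, and the small scenes keep the suite quick to
run anywhere.

## Known limitations

* Oblique (non-axis-aligned) NIfTI affines are rejected rather than
  resampled; inputs are expected in a canonical scanner orientation.
* Height is a centroid chord; the footprint-mean height variant is exposed
  through the bundle radius but is not the default, and very irregular
  (non-convex along z) disks would make any chord definition fragile.
* The exclusion filter operates on manifest flags; it does not itself detect
  pathology, malposition or quality problems.
* Reliability (ICC) machinery is provided, but reliability *values* are
  data properties: the phantom cannot stand in for human intra-/inter-rater
  variability.
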