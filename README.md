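# discmorph

Volumetric morphometry of pediatric intervertebral disks (IVD) from labeled
MRI segmentations, with a calibrated spine-phantom generator for validation.

## The problem

The intervertebral disk — an outer fibrous annulus fibrosus (AF) ring around
a gel-like nucleus pulposus (NP) core — changes shape and composition as
children grow, and those changes are thought to matter for the etiology of
pediatric spinal deformities such as idiopathic scoliosis. Quantifying that
development from T2-weighted MRI requires more than voxel counting: each
disk must be measured in its own anatomical coordinate frame, corrected for
how the patient happened to lie in the scanner.

`discmorph` implements that measurement chain for people working with
labeled AF/NP segmentation volumes (one integer label per disk level and
structure, NIfTI format):

* **Per-disk frames.** Each AF mask defines its inertia axes (eigenvectors
  of the central second-moment tensor of its voxel centres). The axes are
  signed and ordered anatomically (x left–right, y anterior–posterior,
  z cranial–caudal), then the frame is rotated about z until y lies in the
  *patient* sagittal plane — the plane through the AF centroids of T1, L1
  and the most posteriorly positioned AF.
* **Morphometry.** In that frame the package extracts disk height `H` at the
  centre of gravity (mm), transverse cross-sectional area `A` (mm²),
  slenderness

  `S = H / sqrt(A)`,

  the AF, NP and whole-disk volumes with `V_IVD = V_AF + V_NP`, the ratio
  `V_NP : V_IVD` (a hydration proxy), and the offset of the NP centroid
  relative to the whole-IVD centroid along the frame axes.
* **Cohort statistics.** Stratification into SRS level groups
  (upper/mid/low-thoracic, lumbar) and age groups (infantile 0–3, juvenile
  4–10, adolescent 11–18), LOESS growth curves, birth-to-adulthood percent
  changes, OLS age-trend tests, Welch sex comparisons, and two-way
  random-effects ICC (absolute agreement, single measure) for intra- and
  inter-operator segmentation reliability.
* **Spine phantoms.** A synthetic generator produces labeled spine volumes
  (17 AF/NP pairs along a curved sagittal profile, anisotropic voxels) from
  piecewise-linear growth curves calibrated so that, e.g., mid-thoracic
  slenderness at ages 9–13 averages 0.23 for girls and 0.27 for boys and the
  lumbar NP ratio reaches 25 % at age 18. Every phantom disk carries its
  exact ground truth, so the pipeline's accuracy is testable.

## Worked example

Generate one lumbar phantom disk for a 12-year-old girl, voxelize it at
0.5 mm with a small patient pose, and measure it:

```r
library(discmorph)

table   <- default_growth_table()
truth   <- sample_disc_params(table, age = 12, sex = "F", level_index = 15)
phantom <- rasterize_disc(truth, spacing_mm = c(0.5, 0.5, 0.5),
                          pose_deg = c(5, 3, 8), seed = 42)
masks   <- suppressMessages(
  extract_disc_masks(phantom$volume, default_label_schema(17)))
rec <- measure_disc(masks[[1]], sagittal = phantom$sagittal)
round(rec, 3)
```

```
  level_index  H_mm   A_mm2     S V_AF_mm3 V_NP_mm3 V_IVD_mm3 np_ratio off_x_mm off_y_mm off_z_mm
1          15 10.03 1206.88 0.289  8488.25   2435.5  10923.75    0.223    0.001    0.979    0.006
```

The true generative values were height 10 mm, cross-sectional area
1208.6 mm², slenderness 0.288: despite the rotated pose, the corrected frame
recovers height to 0.03 mm and area to about 0.1 %. `off_y_mm ≈ 1` mm is the
anterior nucleus offset the lumbar growth curve prescribes at this age;
`np_ratio ≈ 0.22` says the nucleus holds about a fifth of the disk volume.

For whole scans and cohorts use `run_scan()` / `run_cohort()` (or the CLI in
`inst/cli/discmorph.R` with subcommands `phantom`, `measure`, `cohort`,
`validate`), and `validate_pipeline()` for a self-check report of the
analytic-oracle, rotation-invariance and recovery suites.

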