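Package: discmorph
Title: Pediatric Intervertebral Disk Morphometry from Labeled MRI Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric morphometry of intervertebral disks (IVD) from labeled
    segmentation volumes of the annulus fibrosus (AF) and nucleus pulposus (NP).
    Reconstructs a per-disk anatomical coordinate frame from the AF inertia
    axes with a patient-specific sagittal-plane rotation correction, and
    extracts disk height, transverse cross-sectional area, slenderness
    (height / sqrt(area)), AF/NP/IVD volumes, the NP:IVD volume ratio and the
    nucleus-centroid offset. Includes a calibrated spine-phantom generator
    with known ground truth for validation, cohort-level growth-curve (LOESS)
    and reliability (ICC) statistics, and an end-to-end measurement pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
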