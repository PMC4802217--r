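Package: LongiVol
Title: Longitudinal Multi-Rater Brain Tumor Volumetry and Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing agreement between raters (human experts or
    automatic segmentation methods) in longitudinal brain tumor volumetry.
    Computes compartment volumes from 3-D segmentation label maps, Dice
    overlap with a small-volume exclusion gate, preoperative-normalized
    volumetric trend curves, slope-sign disagreement statistics between
    consecutive time points, log-ratio disagreement plots, and cohort-level
    disagreement matrices. Ships a synthetic cohort generator (acquisition
    schedules, surgery-and-regrowth volume trajectories, rater bias and
    noise models, ellipsoidal label-map phantoms) so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    RNifti
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'agreement.R'
    'disagreement.R'
    'io.R'
    'report.R'
    'schedule.R'
    'simulate.R'
    'volumetry.R'
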