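Package: pelvisct
Title: Synthetic CT Generation and Dosimetric Validation for MRI-Only
    Pelvic Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates synthetic CT (sCT) volumes from Dixon MRI by four
    methods (bulk density assignment, tissue-class density assignment,
    hybrid multi-atlas fusion with local weighted voting, and a
    conditional GAN), and validates them against reference CT with the
    standard MRI-only planning toolkit: Hounsfield-unit mean error and
    mean absolute error with end-slab exclusion, a simplified multi-beam
    attenuation dose engine, DVH metrics, ICRU-point and DVH percentage
    dose differences, 3D gamma analysis with body-perimeter erosion and
    a low-dose threshold, and Mann-Whitney cohort statistics. Ships a
    seeded digital pelvis phantom module that produces paired
    pseudo-CT/pseudo-Dixon-MRI cohorts with ground-truth labels for
    end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
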