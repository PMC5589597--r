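Package: rtpseudo
Title: Pseudo-CT Generation and Dosimetric Verification for MRI-Based
    Brain Radiotherapy Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Generates pseudo-CT volumes for MRI-based brain radiotherapy
    planning by rigidly registering a prior diagnostic CT to the planning
    scan geometry and applying an outer-body Hounsfield-unit correction
    (tissue excess to air, tissue deficiency and unscanned anatomy to soft
    tissue), then verifies the result dosimetrically: a simplified
    heterogeneity-aware photon dose engine computes five-beam plans on the
    pseudo-CT, recomputes them frozen on the reference CT, and compares the
    two with DVH and plan-quality metrics, pixel dose differences, and
    2%/1 mm gamma analysis. A seeded digital head-phantom generator
    provides paired diagnostic/planning scans with realistic acquisition
    differences (gantry tilt, thick slices, limited scan extent,
    inter-scan body change) so the whole workflow runs end-to-end without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
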