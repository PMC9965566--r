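Package: mvdquant
Title: Quantification of Peripapillary Choriocapillaris Microvascular
    Dropout from En-Face OCTA Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies microvascular dropout (MvD, flow voids)
    in 8-bit en-face optical coherence tomography angiography (OCTA) images
    of the peripapillary choriocapillaris. Implements dark-region detection
    by intensity threshold and connected-component area filtering within
    peripapillary atrophy (PPA) zone masks, large-vessel exclusion, per-eye
    zone and flow-density metrics, and cohort-level statistics (group
    comparisons, prevalence, correlation and regression of MvD area on
    refractive covariates). Ships a calibrated synthetic-cohort generator
    that emulates high-myopia and mild-to-moderate-myopia peripapillary
    image and covariate structure so the full pipeline is testable without
    patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, png, yaml, jsonlite
Suggests: testthat (>= 3.0.0), EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
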