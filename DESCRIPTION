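Package: v1phys
Title: Visual Cortex Physiology: AP Metrology, Contrast Sensitivity
    Functions, and Ordinal Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing primary visual cortex physiology in
    genotype-comparison studies: extraction of passive-membrane and
    action-potential features from current-clamp step recordings,
    estimation of neuronal contrast sensitivity functions from
    two-photon calcium imaging traces, cumulative link mixed models
    (ordinal regression with per-animal random intercepts, fitted by
    adaptive Gauss-Hermite quadrature), multiple-testing correction, and
    parvalbumin-positive cell density statistics.  Ships a synthetic-data
    generator with analytic ground truth so every stage of the pipeline
    is testable without raw recordings, plus plain-text exchange formats
    and a command line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
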