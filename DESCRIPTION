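Package: scrubbias
Title: Motion-Scrubbing Exclusion Bias Audit for Resting-State fMRI Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how resting-state fMRI quality-control exclusion
    rules bias the analyzed sample. Computes framewise displacement from
    rigid-body motion parameters, filters respiratory artifact with a zero-phase
    band-stop filter, builds frame-censoring masks with a contiguous-segment
    rule, applies minimum-retained-data inclusion rules across motion
    thresholds, assembles multi-condition exclusion tables, audits
    covariate-exclusion associations with bivariate and adjusted logistic
    odds-ratio models, traces excess missingness across scrubbing thresholds,
    and diagnoses residual motion artifact with QC-FC distance-dependence
    summaries. Includes a synthetic cohort generator with configurable
    covariate, motion, and connectivity structure so the full audit is testable
    without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS,
    withr
Config/testthat/edition: 3
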