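Package: vcfaccuracy
Title: Diagnostic Accuracy Validation for Patient-Level Vertebral
    Compression Fracture Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Validates a patient-level binary vertebral compression
    fracture (VCF) detector against a dual-reader, adjudicated,
    Genant-graded radiologist reference standard.  Implements the full
    validation analysis: construction of the adjudicated reference from
    paired neuroradiologist readings, dichotomization at configurable
    severity thresholds, exact (Clopper-Pearson) binomial confidence
    intervals, likelihood-ratio inference on the log scale, per-vertebral-
    level sensitivity, handling of non-evaluable scans including an
    inclusive sensitivity re-analysis, likelihood-ratio-precision sample
    sizing, and inter-rater reliability via REML variance components with
    bias-corrected accelerated (BCa) bootstrap intervals.  A synthetic
    cohort generator emulates the cohort, rater and detector statistical
    structure so the complete analysis runs with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    boot,
    jsonlite,
    withr
Config/testthat/edition: 3
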