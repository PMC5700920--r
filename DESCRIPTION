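Package: hippocase
Title: Single-Case and Group Inference for Hippocampal Subfield
    Volumetry and MRS
Version: 1.0.0
Authors@R:
    person("Ingrid", "Sollberger", email = "ingrid.sollberger@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for 7T hippocampal imaging studies in
    temporal lobe epilepsy: head-size normalization of manually segmented
    subfield volumes, CSF partial-volume correction and CRLB quality
    filtering of MRS metabolite concentrations, left-right asymmetry
    indices, Box-Cox preconditioned sign-flipping permutation tests of
    single patients against a small control group with family-wise error
    correction and laterality-concordance labelling, group-level ANCOVA
    and clinical correlations, segmentation reliability (repeated-measures
    ANOVA and intraclass correlation), and a synthetic cohort generator
    for calibration and power checks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
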