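Package: methrisk
Title: Composite Methylation Risk Scores from Droplet Digital PCR Liquid Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for blood-based DNA-methylation biomarker analysis with
    bias-based preamplification and droplet digital PCR (ddPCR). Simulates
    patient cohorts and droplet-level two-channel fluorescence wells, inverts
    droplet counts to copies per millilitre of plasma via Poisson occupancy
    statistics, models methylation-specific preamplification bias and screens
    reaction conditions against feasibility criteria, selects candidate CpG
    markers from beta-value matrices with multi-tissue contrasts, calibrates
    additive composite risk scores (methylation markers, cfDNA load, age, and
    optionally the free-to-total PSA ratio) under a 100 percent sensitivity
    constraint, and evaluates cohorts with the standard decision tree of group
    tests, sensitivity/specificity, and ROC/AUC.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, car, jsonlite
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
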