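Package: prscreen
Title: Polygenic Risk-Stratified Cancer Screening Eligibility Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models personalised cancer screening eligibility based on age and
    polygenic risk. Builds the log-normal population distribution of polygenic
    relative risk from published per-allele odds ratios and risk-allele
    frequencies, computes age-conditional absolute risks from incidence and
    mortality rate tables under competing risk of other-cause death, and
    compares age-based with age-plus-polygenic-risk screening strategies:
    eligible population fractions, potentially screen-detectable case
    fractions, reclassification tables, threshold sweeps and matched-threshold
    solving. Includes a calibrated synthetic rate-table generator and an
    individual-level cohort micro-simulator used as a brute-force check of
    every closed-form quantity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
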