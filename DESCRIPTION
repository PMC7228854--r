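Package: mrbattery
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested battery of two-sample Mendelian randomization methods for
    GWAS summary statistics: instrument selection and allele harmonization,
    inverse-variance-weighted meta-analysis of Wald ratios, weighted median and
    weighted mode estimators, MR-Egger regression with I2_GX/NOME assessment and
    SIMEX correction, GSMR with HEIDI outlier filtering, Steiger directionality
    filtering, heterogeneity and instrument-strength diagnostics, a reporting
    policy with explicit gates, and a synthetic summary-statistics generator
    with known causal structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
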