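Package: mrmediate
Title: Two-Sample Mendelian Randomization Screening and Two-Step Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Causal inference from GWAS summary statistics: instrument
    selection with clumping and weak-instrument filtering, allele
    harmonization, five two-sample Mendelian randomization estimators
    (inverse-variance weighted, MR-Egger, weighted median, weighted and
    simple mode), a sensitivity battery (Cochran's Q, Egger intercept,
    leave-one-out, MR-PRESSO outlier detection), Benjamini-Hochberg
    evidence tiers, reverse-MR filtering, and two-step mediation analysis
    with product-of-coefficients effects and delta-method intervals.
    Includes a seeded synthetic summary-statistics generator with known
    causal structure for calibration and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
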