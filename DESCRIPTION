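Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for two-sample Mendelian randomization (MR) on GWAS
    summary statistics, including instrument selection (p-value screening,
    greedy LD clumping, F-statistic filtering), effect-allele harmonization,
    the standard summary-data estimators (inverse-variance weighted, MR-Egger,
    weighted median, weighted mode, simple mode, Wald ratio), sensitivity
    diagnostics (Cochran's Q, MR-Egger intercept, leave-one-out, an
    MR-PRESSO-style global/outlier/distortion test), and two-step MR mediation
    analysis with product-of-coefficients effects, delta-method confidence
    intervals, Benjamini-Hochberg evidence tiering, and a binary-outcome power
    calculator. A synthetic summary-statistic generator produces
    exposure/mediator/outcome trios with known causal structure so that every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
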