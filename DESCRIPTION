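Package: mrpath
Title: Two-Sample and Multivariable Mendelian Randomization with
    Simulation-Based Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for two-sample univariable and multivariable Mendelian
    randomization (MR) from GWAS summary statistics: reading and validating
    summary-statistic tables with explicit column maps, allele harmonization
    with palindrome handling, greedy LD clumping, inverse-variance-weighted
    (IVW), MR-Egger and multivariable IVW estimation with odds-scale
    reporting, Steiger directionality filtering, instrument F statistics,
    Cochran's Q heterogeneity, leave-one-out and funnel diagnostics, and a
    structural simulation engine that generates two-sample GWAS summary
    statistics under explicit causal models (confounding, mediation,
    horizontal pleiotropy, bidirectional and joint effects) so every
    estimator can be validated by parameter recovery against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
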