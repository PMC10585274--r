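Package: mrmediate
Title: Two-Sample and Two-Step Mendelian Randomization with Mediation
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: instrument selection (p-value thresholding, LD clumping,
    variance-explained and F-statistic weak-instrument screening), effect-allele
    harmonization with palindromic-variant handling, causal-effect estimation by
    random- or fixed-effect inverse-variance weighting, MR-Egger regression and
    the weighted median, heterogeneity and pleiotropy diagnostics (Cochran's Q,
    Egger intercept, leave-one-out), and two-step mediation analysis via the
    product-of-coefficients method with delta-method confidence intervals and
    case classification.  Includes a seeded generator of coherent
    exposure/mediator/outcome GWAS summary-statistics tables under a known
    causal chain, so the whole pipeline can be validated against ground truth,
    and a configuration-driven driver for multi-trait analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
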