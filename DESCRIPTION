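Package: rejuvmet
Title: Cross-Species Metabolomic Aging-Signature Reversal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for quantifying
    "metabolic rejuvenation": per-feature differential abundance with
    empirical-Bayes variance moderation, construction of metabolomic aging
    signatures, connectivity-map-style signature-reversal scoring via
    Spearman correlation, random-intercept mixed models with polynomial
    dose terms, cross-condition correlation networks and uncentered PCA,
    Kaplan-Meier survival with log-rank testing, calculated serum
    osmolality, and preranked set enrichment. Includes synthetic-data
    generators that emulate cross-sectional mouse and longitudinal
    dose-escalation human targeted-metabolomics designs so every stage is
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    lme4,
    survival,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
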