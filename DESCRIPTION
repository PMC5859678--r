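Package: mlcfa
Title: Multilevel Confirmatory Factor Analysis for Clustered Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for examining the multilevel factorial structure of
    clustered ("complex survey") data. Decomposes the total sample
    covariance into pooled-within and scaled-between components, computes
    intraclass correlations, and fits one-level confirmatory factor
    analysis (CFA), multilevel CFA (MCFA), and partially saturated models
    (the "maximum" model with a saturated between level, and its
    between-level counterpart) by minimizing Muthen's limited-information
    (MUML) discrepancy. Provides level-specific chi-square tests, CFI,
    RMSEA, SRMR and per-indicator R-squared, congruence diagnostics
    (relative differences and Wald-type t contrasts) between competing
    models, a tabulated three-model comparison, and a two-level normal
    Monte-Carlo generator with a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
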