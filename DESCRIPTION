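Package: mirsens
Title: Analysis of MicroRNA Taxane-Sensitisation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing genome-wide microRNA mimic and inhibitor
    screens that search for taxane sensitisers in cancer cell lines.
    Implements per-plate normalization of viability signals to non-targeting
    controls, dual-threshold hit calling with strength tiers, siRNA
    toxicity/sensitisation classification, doubling-time estimation from
    confluency curves, four-parameter log-logistic dose-response fitting with
    IC20/IC50 inversion, post-differential-expression transcript filters and
    microRNA target-evidence annotation, hypergeometric gene-set
    over-representation testing, tumor-expression evaluation with
    missing-value handling, and seeded synthetic-data generators with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
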