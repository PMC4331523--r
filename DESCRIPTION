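Package: sigscreen
Title: Knockout-Anchored Gene Expression Signatures and Rank-Based Compendium Screening
Version: 0.1.0
Authors@R: person("sigscreen", "maintainers", email = "sigscreen@example.org", role = c("aut", "cre"))
Description: Builds receptor-dependent gene expression signatures from paired
    wild-type/knockout treatment experiments, compares signatures to
    statistically filtered gene lists (biosets) with a fold-change rank-based
    directional similarity test (a running Fisher exact scan), screens
    annotated bioset compendia for activation or suppression calls, and
    evaluates classification accuracy. Includes a synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
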