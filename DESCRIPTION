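Package: cpmnet
Title: Connectome-Based Predictive Modeling of Anhedonia with Depression
    Subtype Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for connectome-based predictive modeling (CPM) of
    behavioral scores from functional-connectivity matrices, with
    leave-one-out cross-validated edge selection, network-strength
    scoring, permutation significance testing, hub-node identification,
    seed-based functional-connectivity group comparison with Bonferroni
    correction, covariate-adjusted partial correlation, and RBF-kernel
    support-vector-machine subtype classification with grid-searched
    parameters. Includes a seeded synthetic cohort generator that
    emulates the statistical structure of a three-group depression study
    (melancholic, non-melancholic, healthy control) so the whole
    pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
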