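Package: ClinicalTrajectories
Title: Temporal Clinical Event Pairs and Disease Trajectories in
    Longitudinal Health Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects statistically significant, temporally directed clinical
    event pairs in longitudinal health-event tables flattened from an
    OMOP-style schema, and composes them into longer disease trajectories.
    Per-patient event histories are reduced to first-occurrence sequences;
    every ordered concept pair within a configurable temporal gap window is
    tested by comparing an exposed group (patients with a prior first event)
    against a background group matched on exact covariates (gender, age
    group, calendar year of the first event) plus a ridge-logistic
    propensity score, using Fisher's exact test for association, relative
    risk with a Katz log-normal confidence interval for effect size, an
    exact binomial test for temporal direction, and false discovery rate or
    Bonferroni multiple-testing correction. Significant directional pairs
    form a directed graph whose simple paths are enumerated and counted
    against the per-patient sequences, allowing intermediate events. A
    synthetic longitudinal data generator with plantable event pairs and
    multi-event trajectories supports end-to-end validation, and discovery
    and validation run modes with privacy masking mirror multi-database
    replication workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    igraph,
    glmnet,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
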