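Package: ecvnet
Title: Sample-Specific Edge Contributions in B-Spline Bayesian Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates gene regulatory networks as nonparametric Bayesian
    networks with additive B-spline regression, quantifies the contribution
    of every network edge to each sample (the edge contribution value, ECv),
    and extracts condition-differential subnetworks from the absolute
    difference of mean ECv between sample groups. Includes an iterated
    subnetwork edge-frequency estimator for the basal network, transfer of
    trained edge models to external expression cohorts, ECv-pattern
    clustering of samples, and survival comparison of the resulting groups.
    A seeded synthetic-data generator emulating a multi-cell-line,
    two-condition replicate design makes the whole workflow testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    igraph,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'splines.R'
    'score-cache.R'
    'local-model.R'
    'model-io.R'
    'structure-search.R'
    'ecv.R'
    'subnetwork.R'
    'cohort.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
    'ecvnet-package.R'
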