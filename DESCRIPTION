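Package: lamhier
Title: Cortical Hierarchy from the Laminar Origin of Interareal Projections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates continuous cortical hierarchies from retrograde
    tracing data using the fraction of supragranular labeled neurons (SLN)
    of interareal projections. Laminar counts are modeled with a
    beta-binomial likelihood whose mean is a probit function of the
    hierarchical-level difference between source and target areas on the
    incidence matrix of the cortical graph; a least-squares identity-link
    alternative, goodness-of-fit and model comparison are included.
    Companion analyses cover pairwise SLN correlations across injections,
    weight-distance rules for feedforward and feedback pathways
    (fractionated FLN regressions, FLN-SLN parabola, distance-binned
    pathway incidence), a regression-stump split of laminar depth
    profiles, and a seeded synthetic-data generator for parameter-recovery
    studies. Ships the published macaque SLN/distance table and
    correlation matrices as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rpart,
    glmmTMB,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
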