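Package: windward
Title: Counterfactual Analysis of Plateau-Uplift Effects on Bird Migration
Version: 0.1.0
Authors@R:
    person("Windward", "Maintainers", email = "maintainers@windward.example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully synthetic reimplementation of a counterfactual
    analysis of how the Qinghai-Tibet Plateau uplift reshaped bird migration.
    Generates seeded synthetic checklists, two-scenario gridded environments
    (modern and a pre-uplift counterfactual with elevation capped at 300 m),
    species truths and tracking routes; filters and hex-subsamples checklists;
    builds the canonical 106-column predictor matrix; fits an adaptive
    spatiotemporal stixel-ensemble abundance model; fits and projects a
    maximum-entropy-style niche model; computes monthly wind-cost connectivity;
    derives great-circle migration segments; and quantifies environmental
    drivers of migratory direction with random-forest and Bayesian
    (hierarchical) regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    glmnet,
    igraph,
    jsonlite,
    yaml,
    splines,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    mgcv,
    withr
Config/testthat/edition: 3
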