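Package: hybcoal
Title: Forward-Time Simulation of Hybrid Species Networks and Gene Tree
    Discordance Statistics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time, event-based simulation of species networks under
    divergence speciation, homoploid hybrid speciation and introgression, with
    distance-dependent hybridization success, piecewise-constant rate epochs and
    a restricted multispecies coalescent that emits gene trees per locus. A
    suite of gene-tree discordance statistics (tree and quartet entropy, split
    incompatibility and its thresholded family, rare and unique splits, distance
    to the majority-rule consensus, unique cherries, internode certainty and
    tree certainty on the greedy consensus) summarises profiles of gene trees,
    and two downstream inference procedures are provided: multinomial scenario
    classification with stepwise-AIC interaction selection, and semi-automatic
    approximate Bayesian computation with regression-derived summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    nnet,
    MASS,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
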