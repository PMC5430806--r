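Package: motenet
Title: Proximity-Sensor Contact Networks, Centrality and Maternal Fitness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds weighted social contact networks from wearable
    proximity-sensor ("mote") ping logs, computes five node centrality
    measures (degree, strength, eigenvector, betweenness, closeness) with
    per-camp standardization, derives age-controlled reproductive-success
    residuals from living-offspring counts via Poisson regression, and fits
    the two-standard-deviation standardized regression suite linking
    maternal network centrality to fertility residuals and reported
    sickness, including variance-inflation-factor screening, age-interaction
    pruning and dependent-count mediation checks. Ships a synthetic
    mote-data generator with planted effects so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    car,
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
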