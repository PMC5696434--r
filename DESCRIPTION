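Package: driftlag
Title: Forward-Time Simulation of Isolation by Drift and Its Detection Lag
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based, forward-time simulation of genetic drift in
    long-lived populations with overlapping generations, built to measure
    how many years after a fragmentation event (for example a dam that
    blocks host-fish mediated dispersal of freshwater mussel larvae)
    genetic divergence between the isolated and the source population
    becomes detectable.  Populations of constant census size are founded
    from per-locus microsatellite allele frequencies, aged under a fixed
    annual survival probability with a maximum-lifespan cap, and renewed
    by random mating with Mendelian inheritance.  The detection layer
    re-implements the three standard analyses applied to such data:
    the Weir-Cockerham (1984) multi-locus FST estimator, assignment by
    discriminant analysis of principal components (DAPC), and Bayesian
    admixture clustering with model choice by mean estimated ln P(K).
    An experiment module runs seeded replicate grids over census size and
    maximum lifespan and aggregates detection-frequency curves.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
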