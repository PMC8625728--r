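Package: rxqueue
Title: Queuing Model of Saturable Receptor-Based Molecular Communication
    Receivers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-form and stochastic models of a diffusion-based
    molecular-communication receiver whose surface receptors saturate.
    Each receptor is treated as an M/M/1/1 loss queue fed by a
    non-homogeneous Poisson stream of diffusing ligands: the package
    provides the time-varying hitting fraction for an n-receptor
    spherical receiver in a numerically stable scaled-erfc form,
    capture-probability and recapture feedback, per-receptor and
    aggregate absorption/rejection rates with cumulative counts, a
    receptor-occupancy (binomial/normal) layer with release-rate
    inversion for dose planning, a seeded queue-bank simulator that
    validates the closed forms, and a Brownian-dynamics Monte-Carlo
    oracle for the absorbing-sphere first-passage limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
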