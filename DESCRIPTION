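Package: crossflow
Title: Laminar Flow, Particle Tracing and Neural Surrogates for
    Microfluidic Cross Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design tools for particle-sorting microfluidic chips built from
    straight channels and four-port cross junctions. Provides a masked
    staggered-grid Stokes solver for the steady laminar velocity field in a
    cross junction under prescribed port velocities, a Stokes-drag particle
    tracer with finite-size freeze-on-wall capture, a randomized generator of
    intersection cases and 7-feature / 60-coordinate trajectory training
    records, a chained three-block dense-network surrogate that predicts
    entrance, middle and exit trajectory segments, and a hydraulic
    resistor-network composer that assembles whole-chip particle paths from
    per-unit predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
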