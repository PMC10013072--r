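Package: oaburst
Title: Collective Activity Bursting in Excitable Rotator Populations with
    Slow Resource Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a two-layer multiscale model in
    which a heterogeneous population of globally coupled excitable active
    rotators interacts adaptively with a slow oscillatory pool of
    resources.  Provides direct microscopic simulation of the coupled
    system, the Ott-Antonsen mean-field reduction of the fast layer
    dynamics on a fixed heterogeneity quadrature grid, stationary-state
    analysis through a self-consistency equation for the effective
    excitability parameter, linear stability via continuous and discrete
    spectra of the linearized mean-field operator, two-parameter fold and
    cusp mapping with regime diagrams, and slow-fast experiments covering
    collective activity bursting, adiabatic parameter sweeps and
    perturbation-induced switching between coexisting macroscopic
    regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    pracma,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
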