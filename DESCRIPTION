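Package: reeftda
Title: Stochastic Spatial Coral-Reef Dynamics and Topological Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a stochastic, spatially explicit lattice model of
    competition between coral, algal turf and macroalgae on a reef, and
    provides multiscale spatial descriptors for its output: neighbourhood
    composition statistics, persistent homology of coral density
    filtrations built on cubical complexes, zigzag persistence of coral
    components through time, and persistence landscapes averaged over
    stochastic realizations.  Includes the mean-field limit as a
    deterministic ODE, outcome classification for bistability experiments,
    grazing-rate sweeps, readers and writers for grid snapshot formats,
    and a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
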