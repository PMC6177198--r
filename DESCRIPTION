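Package: aspidyn
Title: Individualised Aspiration Dynamics for Multiplayer Games on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stochastic simulation and exact analysis of aspiration-based
    (self-evaluation) strategy updating for two-strategy d-player games in
    finite structured populations. Provides a Monte-Carlo engine for
    well-mixed, ring, regular, random and scale-free populations with
    per-individual aspiration levels, an exact stationary-distribution
    solver for small populations, the weak-selection sigma-rule criterion
    with binomial structure coefficients, and a regression protocol that
    recovers the coefficients from simulated stationary abundances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
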