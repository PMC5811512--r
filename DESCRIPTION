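Package: openblock
Title: Kinetics of Open-Channel Block in Linear Markov Models of Ion Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical and stochastic machinery for linear Markov models of
    voltage-gated ion channels blocked in the open state (C <-> ... <-> O <-> B).
    Builds tridiagonal generator matrices for Hodgkin-Huxley-type schemes with
    m independent gates plus a blocked state, solves the master equation
    exactly by eigendecomposition (with Putzer-recursion and matrix-exponential
    oracles), decides whether the open-probability waveform has an
    inactivation-like interior peak, computes closed-form peak time and
    relative peak height, maps peak behaviour over voltage via Eyring-Polanyi
    rate theory, and validates everything with exact Gillespie simulation of
    channel ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
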