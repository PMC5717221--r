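Package: lgcarw
Title: Lattice-Gas Cellular Automaton Models for Time-Correlated Random
    Walks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Seeded stochastic simulation and analytic theory for
    lattice-gas cellular automaton (LGCA) random walks with memory:
    the classical unbiased walk, the persistent walk with a
    Boltzmann-like reorientation kernel, the time-correlated walk whose
    reorientation probabilities are derived from a prescribed velocity
    autocorrelation function (VACF), and the generalized time-correlated
    walk obtained by maximum-caliber (path entropy) inference.  Provides
    per-step reorientation kernels, closed-form VACF and mean-square
    displacement curves together with adaptive-quadrature oracles,
    diffusion-regime classification (sub-, normal and superdiffusion),
    a Markov-chain VACF trichotomy toolkit, and ensemble estimators for
    the VACF, MSD, diffusion coefficient and anomalous exponent.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
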