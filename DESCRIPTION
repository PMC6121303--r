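Package: pumploop
Title: Linked Markov, Thermodynamic, Wave-Superposition and Oxidant-Loop
    Models of Na/K-ATPase Pumping and Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the dual pumping and signaling functions of the
    Na/K-ATPase (sodium pump) with three linked models: a discrete-time
    Markov chain over the Post-Albers conformational cycle (E1, E1P, E2P,
    E2) with stationary distributions, hidden-state expansion and path
    sampling; a continuous-time master equation over the kinetic cycle
    with nonequilibrium steady-state cycle flux and entropy production; a
    plane-wave superposition of spatially and frequency-separated
    "signaling" and "pumping" pump pools with Fourier power-spectrum
    readout and an ouabain-induced E2:E1 shift; and an ordinary
    differential equation model of the feed-forward oxidant amplification
    loop coupling pump conformation, Src kinase phosphorylation, reactive
    oxygen species, pump endocytosis and cumulative aging.  Includes
    basal-state calibration, perturbation experiments, scenario runners
    with deterministic file outputs, broom-style tidiers and ggplot2
    autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
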