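Package: painseq
Title: Statistical Learning Models of Pain Perception and Prediction in
    Noxious Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying statistical learning in sequences of noxious
    (thermal pain) stimuli. Generates chunked intensity sequences under a 2x2
    volatility-by-stochasticity design, implements five confidence-weighted
    observer models (Rescorla-Wagner reinforcement learning, its
    expectation-weighted extension, the Kalman filter, the expectation-weighted
    Kalman filter, and a random-response baseline), fits them hierarchically by
    MCMC with non-centred parametrisation, compares them by PSIS-LOO expected
    log predictive density with a sigma-effect heuristic, contrasts posterior
    parameters between conditions via highest-density intervals, and runs
    parameter- and model-recovery simulation studies on fully synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble
Suggests:
    jsonlite,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
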