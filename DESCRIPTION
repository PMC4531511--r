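Package: pbbn
Title: Probabilistic Bipartite Boolean Networks from Reaction-Contingency Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts reaction-contingency network definitions of cellular
    signaling systems into bipartite Boolean models, and extends them to
    probabilistic Boolean networks in which quantitative contingencies (K+/K-)
    are encoded as ordered update functions with probabilities controlled by
    two global parameters: a false-rate (random reaction failure) and a
    k-base (preference for more restrictive update functions). Includes a
    synchronous stochastic simulator with ensemble averaging, perturbation
    (clamping) schedules, an exact Markov-chain oracle for small models,
    ensemble analysis of oscillation amplitude, phase, desynchronization and
    convergence, bundled fixtures (a simplified high-osmolarity-glycerol
    pathway oscillator and a random network generator), writers for the
    BooleanNet and BoolNet text dialects, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    parallel,
    generics,
    ggplot2,
    optparse,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
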