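Package: sleepdyn
Title: Recurrence and Complexity Analysis of Neural Population Dynamics
    Across the Sleep-Wake Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how slow-wave sleep reshapes the dynamics of
    simultaneously recorded neuronal populations. Spike trains are binned
    into population phase-space trajectories and characterised by
    recurrence quantification analysis (recurrence rate, determinism,
    laminarity, trapping time, divergence); DOWN/OFF states are detected
    and related to recurrences; synthetic local field potentials are built
    from excitatory spiking and scored with permutation entropy, sample
    entropy and Lempel-Ziv complexity; neuronal avalanches are extracted
    and tested against crackling-noise scaling; and a critical branching
    network with periodic noise silencing reproduces the sleep-like
    complexity reduction. Includes a synthetic session generator with
    ground-truth state labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
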