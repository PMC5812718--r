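Package: multipatchr
Title: Discrete-Event Simulation of Multi-Pipette Automated Patch Clamp
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the control logic of a multi-pipette automated in vivo
    whole-cell patch-clamp ("autopatching") robot against a synthetic
    electrophysiology rig. Provides a seal-test signal chain (square-wave
    stimulus synthesis, triangular moving-average and exponential settling
    filters, peak-to-peak resistance estimation), a stochastic ground-truth
    model of pipettes in brain tissue (descent clogging, neuron encounters,
    inter-pipette mechanical dislodgement, gigaseal formation and break-in),
    a finite-state controller implementing three multi-pipette coordination
    strategies (synchronous, retract-and-replay, interleaved
    halt-and-gigaseal), and campaign-level yield and timing statistics with
    deterministic fixtures encoding published stage counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
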