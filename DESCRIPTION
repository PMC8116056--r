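Package: homecage
Title: Closed-Loop Simulation and Analysis of Autonomous Home-Cage
    Behavioral Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates an autonomous home-cage system that trains mice in
    voluntary head-fixation and a delayed-response tactile decision task,
    and analyses the resulting behavior.  Provides deterministic state
    machines for single trials (epoch timing, lick registration,
    early-lick policy), head-fixation training with an adaptive
    self-release threshold controller, staged task training with
    auto-assist programs, contingency reversal, and optogenetic trial
    scheduling; a generative mouse agent that closes the loop and serves
    as a synthetic-data generator; a choice-strategy logistic regression
    stack with history-excluding cross-validation, partial-model
    bootstrap selection and shuffle controls; nested
    (mouse/session/trial) bootstrap inference for photostimulation
    effects; and spike-rate modulation metrics for optogenetic
    electrophysiology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
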