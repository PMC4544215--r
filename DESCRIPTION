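Package: rsvpTriage
Title: Single-Trial EEG Classification and Confidence-Gated Triage for RSVP
    Target Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for rapid serial visual
    presentation (RSVP) target-detection experiments in which rare,
    target-like non-target stimuli degrade both behavior and single-trial
    EEG classification. Provides a synthetic-session generator (constrained
    stimulus sequences, P3-like evoked responses, button presses), the
    standard preprocessing chain (Butterworth band-pass, decimation,
    epoching, baseline correction), signal-detection behavioral metrics
    (hit rate, false-positive rate, d-prime), class-conditional ERP
    summaries, xDAWN spatial filtering via the SSNR generalized
    eigenproblem, Bayesian linear discriminant analysis with
    evidence-maximized hyperparameters, a distance-to-boundary confidence
    measure, and nested contiguous 10-fold cross-validated evaluation with
    confidence-threshold sweeps and a simulated manual-relabeling
    mitigation strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    Matrix,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
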