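Package: rlerp
Title: Single-Trial Reinforcement-Learning Prediction Errors and Feedback-Locked ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a probabilistic feedback-based learning task with
    learnable (90/10) and distractor (50/50) stimuli under immediate and
    delayed feedback, fits Rescorla-Wagner action-value models with a softmax
    choice rule by gamma-penalized maximum likelihood, exports single-trial
    signed and unsigned reward-prediction-error regressors, scores
    feedback-locked EEG epochs for single-trial FRN, P3a and P3b amplitudes
    (condition-average peak localization, windowed means, amplitude-based
    artifact rejection), computes block accuracy and trial-level choice
    switching, and fits the associated linear mixed models with stepwise
    random-effect reduction, Satterthwaite inference, simple-slope probing and
    Cook's-distance screening. A synthetic-data generator produces complete
    studies (agents, behavior, single-trial amplitudes, continuous EEG) with
    known ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    zoo,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
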