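Package: pigeonbound
Title: Simulation and Trialwise Analysis of Explicit Evidence-Accumulation Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how decision-makers terminate evidence
    accumulation when the decision variable is an explicitly displayed biased
    random walk (a pigeon drifting toward one of two seed piles). Provides a
    generative model of task blocks with configurable payoffs, signal-to-noise
    ratios, and within-trial changepoints; a synthetic-cohort simulator of
    bounded-accumulation agents with non-decision times and fast guesses;
    trialwise estimators of non-decision time (by choice congruence), decision
    time, and decision bounds, with a simulation-based correction for
    short-decision-time measurement bias; Monte-Carlo reward-rate functions of
    bound height for fixed, mixed-SNR, and changepoint designs, with optimal
    bounds and reward-rate gradients; and an end-to-end analysis pipeline with
    parameter-recovery diagnostics.
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
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
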