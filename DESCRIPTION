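Package: nfnirs
Title: Closed-Loop fNIRS Neurofeedback Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing closed-loop functional
    near-infrared spectroscopy (fNIRS) neurofeedback experiments that
    feed back oxygenated-haemoglobin (HbO) activity from a single
    target channel. Implements the full online processing chain
    (causal device filtering, per-trial correlation-based signal
    improvement (CBSI), baseline normalisation, feedback-value mapping
    with adaptive thresholds, and reward accrual), offline quality
    control (coefficient-of-variation and flat-line channel screening,
    trial interpolation, outlier replacement) with robustness
    re-analyses (stringent band-pass filtering, common average
    reference), neurofeedback success metrics (run and participant
    classification, maintenance and improvement tests, sensitivity
    analysis via the noncentral t distribution), and a Posner-cueing /
    visual perspective-taking behavioural pipeline with harmonic-mean
    reaction-time summaries. A synthetic-data module generates
    multi-channel HbO/HbR recordings, block schedules, and behavioural
    trial tables with known ground truth so every stage can be tested
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
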