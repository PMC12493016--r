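Package: soclas
Title: Closed-Loop Acoustic Stimulation and Sleep EEG Event Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing slow-oscillation-targeted
    closed-loop acoustic stimulation (CLAS) experiments in sleep EEG. Provides
    a deterministic replay implementation of an online slow-oscillation
    detector with adaptive negativity threshold, delta/theta gating and
    paired-burst scheduling; offline detectors for slow oscillations
    (zero-crossing half-wave criteria with relative amplitude thresholds) and
    sleep spindles (individual peak frequency, RMS thresholding with merge
    rules); Welch power spectra and stimulus-locked averaging with baseline
    normalisation; a statistics layer with exact paired Wilcoxon signed-rank
    tests, running pointwise tests under Benjamini-Hochberg false discovery
    rate control, and sleep-architecture summaries; and a seeded synthetic
    polysomnography generator with ground-truth event records so the whole
    pipeline is testable without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
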