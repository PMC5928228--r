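Package: finchloop
Title: Closed-Loop Operant Conditioning Simulation for Songbird Vocal and Place Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates closed-loop conditioning experiments in which zebra
    finch-like agents receive pitch-contingent or perch-contingent feedback
    (band-limited noise bursts or strobe-light events), and recovers the
    behavioral read-outs of such experiments from the resulting logs.
    Includes harmonic-stack song synthesis, amplitude-based syllable
    segmentation with spectral-feature and inter-onset-interval targeting,
    short-window FFT pitch estimation with an adaptive median-ratchet
    threshold, exact stimulus timing (75 ms noise or strobe, jittered 2 Hz
    repeats), a two-agent reinforcement architecture in which noise and
    strobe carry different valence for the vocal and navigation systems,
    and a metrics/statistics stage (landing rate, occupancy,
    singing/non-singing split, daily pitch change, t tests, two-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    car,
    jsonlite,
    withr,
    tibble
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
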