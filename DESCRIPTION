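Package: avpipe
Title: Active Versus Passive Vision Analysis for V1 Laminar Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of primary visual cortex (V1) single-unit
    activity recorded during free viewing of natural images, contrasting
    passive vision (responses aligned to image onset, 'img-on') with active
    vision (responses aligned to self-initiated fixation onset, 'fix-on').
    Provides dual-threshold saccade/fixation detection from gaze traces,
    spike-train curation (waveform re-clustering, refractory-violation
    screening, cluster merging, firing-rate change-point segmentation),
    kernel-bandwidth-optimized peri-stimulus time histograms with peak
    latency and significance testing, lifetime sparseness, gaze-contingent
    image contrast and orientedness scoring with contrast matching, laminar
    current source density estimation with layer assignment, a synthetic
    free-viewing session generator with full ground truth, and a study
    orchestrator producing responsiveness, latency and sparseness reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    mclust,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
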