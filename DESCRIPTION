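Package: updownphase
Title: Up/Down State Detection and Spike-LFP Phase-Locking Analysis of
    Cortical Slow Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cortical slow-oscillation dynamics from
    extracellular and intracellular recordings. Detects up and down states
    from the local field potential by combining low-frequency phase
    likelihoods with 10-40 Hz envelope power, thresholded through a
    three-Gaussian mixture, and validates the detection against
    membrane-potential ground truth with ROC analysis. Quantifies spike-LFP
    phase locking on occupancy-rescaled phases (Rayleigh test, circular
    median and interquartile range), scans locking strength across LFP time
    shifts to delimit putative causal windows (tau_max, tau_end), and tests
    spike-triggered changes in LFP phase speed against matched spike-free
    controls. Includes a seeded synthetic-recording generator (alternating
    states, bimodal membrane potential, phase-anchored LFP, entrained or
    causal interneuron spike trains), optogenetic trial analyses (MUA
    detection, PSTH, spectrogram, gamma band power, trial classification,
    transition latency and slope), and light-cone geometry estimates of the
    optogenetically modulated tissue volume and cell count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
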