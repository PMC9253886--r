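Package: lfprhythms
Title: Sleep-State, Oscillation and Coupling Analysis of Two-Site LFP Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for long-duration two-channel local field
    potential (LFP) recordings from ventral hippocampal CA1 and medial
    prefrontal cortex. Provides zero-phase FIR band filtering with a
    tap-count rule tied to the sampling rate, vigilance-state classification
    (AWAKE/NREM/REM) from Gaussian-mixture fits of RMS band-power ratios and
    an activity trace, 1/f-whitened spectral-peak tracking with circadian
    sine fits, theta-gamma phase-amplitude and frequency-amplitude coupling
    (Kullback-Leibler modulation index), inter-site delta-band phase
    synchrony (intersite phase clustering), sharp-wave-ripple and sleep
    spindle detection with coupling, burstiness and memory statistics of
    event trains, and non-parametric effect-size statistics (Cohen's d,
    rank tests, Dunn-Holland-Wolfe multiple comparisons). A synthetic
    two-channel LFP generator with per-second ground truth exercises every
    stage without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
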