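Package: spikefield
Title: Spike-Field Coupling, Cross-Frequency Coupling and Co-Firing
    Analysis for Microwire Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of simultaneously recorded spike trains and local
    field potentials (LFP) from microwire bundle electrodes. Implements
    LFP preprocessing (low-pass filtering, spike interpolation, line-noise
    template subtraction, amplitude-based artifact rejection and
    Gram-Schmidt local re-referencing), single-/multi-unit classification
    from waveform variability and inter-spike intervals, Morlet-wavelet
    and Hilbert phase estimation, spike-field coupling via the pairwise
    phase consistency (PPC) with Rayleigh/FDR screening and shuffle-based
    pair-count nulls, phase-slope-index directionality, peak-matched
    theta-gamma phase-amplitude coupling (modulation index) with waveshape
    asymmetry controls, and shuffle-normalized spike-train
    cross-correlation latency analysis. A synthetic-session generator with
    exposed ground truth (non-stationary theta, theta-locked gamma bursts,
    von-Mises phase-locked spiking, lagged co-firing pairs) makes every
    stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
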