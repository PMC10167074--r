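Package: neuropac
Title: Stimulus-Locked, Spectral and Cross-Frequency Coupling Analysis of
    Neurophysiological Recordings
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the analysis of intracellular and extracellular
    electrophysiology recordings: reading Axon Binary Format (ABF) and
    European Data Format (EDF) files, stimulus detection and peristimulus
    trial segmentation, event-related potential averaging, rectified-RMS
    z-score maps, EPSP slope and latency measurement, Butterworth band
    filtering with analytic envelope and instantaneous phase, FFT and Welch
    power spectra with (relative) band power, Morlet wavelet scalograms,
    three phase-amplitude coupling estimators (Kullback-Leibler modulation
    index comodulograms, wavelet phase-binned power, and a cycle-detection
    variant for intermittent slow rhythms), and two-channel phase coherence.
    Includes deterministic synthetic-signal generators with known coupling
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io-edf.R'
    'io-abf.R'
    'io.R'
    'segmentation.R'
    'timedomain.R'
    'spectral.R'
    'timefreq.R'
    'coupling.R'
    'synth.R'
    'cli.R'
    'neuropac-package.R'
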