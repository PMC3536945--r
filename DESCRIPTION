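Package: gaborclean
Title: Gabor-Atom Reduction of Muscle Artifacts in the Gamma Band of Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects individual scalp and neck muscle (EMG) spikes in
    high-sampling-rate EEG, fits each one with a Gabor atom (a sinusoid
    under a Gaussian envelope) and subtracts the fitted waveform, so that
    gamma-band (65-85 Hz) neural oscillations can be measured with less
    myogenic contamination.  Includes the surrounding pipeline: power-line
    harmonic regression cancellation, saccade-muscle-potential regression,
    sliding Hanning-windowed FFT time-frequency analysis, adaptive
    amplitude-threshold epoch rejection, and event-related gamma
    synchronisation statistics, together with a seeded synthetic-EEG
    generator with ground-truth spike and burst inventories for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
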