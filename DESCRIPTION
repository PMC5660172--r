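Package: tauconn
Title: Network Oscillations, Connectivity and Evoked Potentials in Multichannel Rodent EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multichannel rodent EEG studies of
    hippocampal-prefrontal network function: relative Welch power spectra
    with 1 Hz aggregation, pairwise magnitude-squared coherence, theta-gamma
    phase-amplitude cross-frequency coupling (modulation-index comodulograms
    with circular-shift surrogate significance), passive-oddball auditory
    evoked potentials (P1/N1/P2/N2 components, mismatch-negativity complex
    amplitudes, Morlet evoked-oscillation power), and DAB-positive-area
    quantification of immunohistochemistry micrographs.  A synthetic-data
    generator produces recordings with known oscillator amplitudes, shared
    sources, coupling strength, event-related templates and two-group effect
    profiles, so every stage of the pipeline can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
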