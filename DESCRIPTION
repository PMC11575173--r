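Package: striatools
Title: Striatal Electrophysiology Analysis: PSC Detection, Spike Metrics,
    E-I Bootstrap Contrasts and LFP Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for striatal electrophysiology recordings:
    hybrid detection of spontaneous excitatory and inhibitory postsynaptic
    currents from voltage-clamp traces; short-term-plasticity quantification
    of evoked 20 Hz pulse trains; bootstrap resampling of excitation-
    inhibition group contrasts; spike-train quality control, waveform
    classification and burst indices; multitaper spectral analysis of local
    field potentials with oscillatory burst-event detection. Includes a
    synthetic-data generator with known ground truth for every input
    modality, so the full pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
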