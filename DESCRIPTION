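Package: eegbci
Title: Single-Channel EEG Rhythm Decomposition and Online Perceptron
    Brain-Computer Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a minimal single-channel electroencephalography (EEG)
    brain-computer interface: streaming acquisition of 10-bit analogue-to-digital
    converter samples (replay files, a self-synchronizing 2-byte serial frame
    codec, and a seeded synthetic EEG generator), decomposition of a rolling
    sample buffer into the clinical rhythm bands (delta, alpha, three beta
    sub-bands, gamma) with linear-phase FIR or Butterworth IIR band-pass
    filters, band-amplitude feature extraction including the alpha-to-raw
    amplitude ratio, a small sigmoid perceptron network trained online with one
    of four algorithms (perceptron error-correction rule, backpropagation,
    resilient backpropagation, Levenberg-Marquardt), a timed eyes-open /
    eyes-closed marker-session protocol, and accuracy scoring of session logs
    against the marker schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
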