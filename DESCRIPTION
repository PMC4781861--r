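Package: plavdet
Title: Seizure Prediction and Detection from EEG Phase and Amplitude Lock Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for patient-specific seizure prediction and detection from
    scalp EEG using sliding-window phase lock values (PLV) and amplitude lock
    values (ALV) between a high-variance working electrode and a low-variance
    reference electrode. Covers equiripple (Remez) band-pass filtering with
    zero-phase application, Hilbert analytic amplitude/phase decomposition,
    patient-specific threshold calibration from lock-value histograms,
    prediction/seizure marker extraction under the seizure prediction horizon
    (SPH) / seizure occurrence period (SOP) framework, Poisson chance-predictor
    significance statistics, EDF and seizure-summary I/O, and a coupled
    noisy-oscillator EEG simulator with ground-truth annotations for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
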