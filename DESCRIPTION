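Package: ictalkit
Title: Electrographic Seizure Quantification and Behavioral Seizure
    Flagging for Rodent Hippocampal LFP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated quantification of electrographic seizures in chronic
    single-channel local field potential (LFP) recordings from rodent models
    of temporal lobe epilepsy, as used with the intrahippocampal kainate
    model. Detects suprathreshold ictal spikes with width and refractory
    constraints, assembles them into seizures by a spikes-per-bin density
    rule with a minimum interictal gap and minimum duration, classifies
    hippocampal paroxysmal discharges, and flags candidate large behavioral
    seizures with an FFT bandpass envelope pipeline. Includes a
    ground-truthed synthetic LFP generator for validating detectors,
    behavioral metrics (discrimination index, memory-test exclusion rules,
    sucrose-consumption and Racine/LBS burden summaries), EDF and raw-binary
    recording I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
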