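Package: erdtraj
Title: Longitudinal EEG Desynchronization Trajectories as Biomarkers of Motor Recovery
Version: 0.1.0
Authors@R:
    person("erdtraj", "developers", email = "erdtraj@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal sensorimotor EEG biomarkers of
    upper-limb motor recovery after stroke. Covers the full offline analysis
    chain for brain-machine-interface training data: reading multichannel
    EEG/EMG recordings (EDF, BrainVision), epoching trials into rest,
    preparation and movement phases, a fully automated artifact-rejection
    cascade (ICA-based ocular artifact removal, z-score detectors for cranial
    EMG and offset artifacts, waveform-length detection of compensatory muscle
    contractions), Welch band-power and event-related desynchronization (ERD)
    extraction with individual sensorimotor-rhythm calibration, and a
    two-stage statistical model that links per-subject ERD trajectories
    (linear mixed-effects intercepts and slopes) to clinical improvement,
    including a progressive laterality coefficient. A synthetic-cohort
    generator with known ground truth makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
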