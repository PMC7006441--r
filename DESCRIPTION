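Package: gaitSPM
Title: Gait Neuromuscular Waveform Analysis with One-Dimensional
    Statistical Parametric Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of surface electromyography (EMG) and
    inertial-sensor gait recordings. Extracts EMG linear envelopes
    (Butterworth band-pass, analytic-signal rectification, 6 Hz
    smoothing), normalizes waveforms to the 0-100% gait cycle, computes
    antagonist co-contraction index curves, detects EMG burst on- and
    offsets by exact one-dimensional k-means clustering with
    duration/gap cleaning rules, reconstructs sagittal hip, knee and
    ankle angles from quaternion orientation streams, detects gait
    events from shank angular velocity, and compares groups of subjects
    over the whole gait cycle with random-field-theory based
    one-dimensional statistical parametric mapping (SPM), including
    cluster p-values, Cohen's d effect sizes and a priori power
    computation. A synthetic-data module generates gait sessions with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
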