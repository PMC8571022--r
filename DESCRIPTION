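Package: microstates
Title: Resting-State EEG Microstate Segmentation and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Segmentation of multichannel resting-state EEG into quasi-stable
    topographic microstates and extraction of their temporal parameters.
    Implements the full analysis chain: preprocessing (polyphase resampling,
    zero-phase FIR band-pass and notch filtering, bad-channel detection with
    spherical-spline interpolation, average referencing, amplitude-based
    window rejection, epoching), polarity-invariant Atomize and Agglomerate
    Hierarchical Clustering (AAHC) of global-field-power peak maps,
    permutation-based group template aggregation and canonical A-D labelling,
    per-sample backfitting, duration/occurrence/coverage/transition parameter
    extraction with global explained variance, and a normality-gated group
    statistics battery (t / Mann-Whitney, Pearson correlation, linear
    regression, ANCOVA, observed-versus-expected transition tests). A
    synthetic-EEG generator with known embedded microstate structure provides
    ground truth for validation, and BrainVision / EDF readers ingest real
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
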