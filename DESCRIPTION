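Package: froikit
Title: Validation of fMRI Localizer Paradigms with Synthetic BOLD and
    Subject-Specific fROIs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for validating blocked
    fMRI localizer paradigms. Builds the trial/block/run timing of standard and
    speeded reading localizers and a spatial working-memory task, simulates
    multi-subject 4D BOLD data with known ground-truth condition amplitudes,
    parcel-constrained selective voxel populations, inter-subject topographic
    jitter, low-frequency drift and AR(1) noise, fits prewhitened first-level
    general linear models, defines group-constrained subject-specific
    functional regions of interest (top-fraction voxels within parcels),
    extracts cross-validated condition responses, and compares localizer
    versions via Fisher-transformed spatial correlations, Dice overlap of
    fROIs, and linear mixed-effects models with crossed random intercepts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    lme4,
    lmerTest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
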