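Package: tmspattern
Title: Multivoxel Pattern Analysis of Concurrent TMS-fMRI Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing interleaved transcranial magnetic stimulation
    (TMS) fMRI experiments in which TMS pulses are locked to slice acquisition.
    Provides slice-locked stimulation schedules, a synthetic 4D BOLD generator
    whose conditions differ in multivoxel pattern but not in mean activity,
    TMS slice-artifact interpolation and outlier repair, fiducial-capsule coil
    localization with entry-line spherical regions of interest, GLM and FIR
    estimation, and Gaussian naive Bayes decoding with leave-one-run-out
    cross-validation, cross-frequency generalization and Gini information-gain
    voxel selection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
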