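Package: ecgddd
Title: ECG-Based Drunk-Driving Detection with Weighted Composite Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for detecting alcohol-affected drivers from
    single-lead electrocardiogram (ECG) recordings. Provides a synthetic ECG
    cohort generator with controllable per-class morphology shifts, a
    Pan-Tompkins style QRS detection and beat-segmentation chain, P/Q/R/S/T
    wave delineation with P-wave duration measurement, extraction of a
    10-dimensional feature vector (means and variances of P, R, S amplitudes
    and R-R intervals, plus maximal P-wave duration and P-wave dispersion),
    correlation-weighted composite kernels over four base kernel families,
    a dual support-vector-machine solver for custom kernels, and stratified
    10-fold cross-validated accuracy/sensitivity/specificity reporting.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
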