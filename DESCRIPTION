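Package: phenolfp
Title: Phenotyping Hippocampal and Prefrontal LFP Dynamics with Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for phenotyping hippocampal (HPC) and medial
    prefrontal cortex (mPFC) local field potential dynamics alongside rodent
    behavior. Provides artifact-robust LFP pre-processing (generalized extreme
    Studentized deviate outlier rejection, gap interpolation, zero-phase FIR
    high-pass filtering, z-scoring), movement/stationary epoching from video
    tracking, epoch-wise power spectra with theta-band summaries, theta-gamma
    phase-amplitude coupling via filter-Hilbert with resultant vector length
    and comodulograms, sharp-wave ripple detection with incidence-rate
    summaries, an estimation-statistics layer (BCa bootstrap mean differences,
    permutation tests, correlation/regression slope comparison, Wilcoxon
    signed-rank against chance), and a synthetic-data generator with full
    ground truth for validating every stage, plus end-to-end T-maze and
    open-field workflow drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
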