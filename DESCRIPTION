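Package: stridefiber
Title: Fiber-Photometry and Locomotion Analysis for Striatal Circuit Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for head-fixed treadmill and open-field
    experiments combining fiber photometry with behavior and optogenetic
    stimulation. Implements two dialects of isosbestic-referenced dF/F
    normalization (sliding-percentile baselining with zero-phase Butterworth
    filtering and RANSAC regression for locomotion recordings; direct RANSAC
    referencing of demodulated traces for stimulation recordings), session
    quality control and z-scoring, rule-based segmentation of movement,
    ambulation and immobility bouts, event-aligned timing metrics (peak time,
    sliding-window rise-time detection, pre-offset slope), quantification of
    stimulation-locked responses (initial elevation, maximal reduction,
    post-stimulation rebound) and epoch-wise velocity summaries. A synthetic
    session generator with exact ground truth (photobleaching, shared motion
    artifacts, event-locked transients, bout-structured velocity) supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    tibble,
    readr,
    yaml,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
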