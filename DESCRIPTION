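Package: nmedian
Title: Memory-Less Streaming Median Estimation for Real-Time Spike Detection
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A memory-less streaming median estimator that keeps a fixed-length
    always-sorted buffer and drops the extreme opposite the side where each new
    sample is inserted, so the central element tracks the signal median without
    any arrival-time bookkeeping.  Includes the classical moving (sliding
    window) median baseline, a truth-table-level software model of the sorting
    cell array used by hardware realisations, robust noise-sigma estimation
    from the median of the rectified signal, threshold-crossing spike detection
    for extracellular recordings, synthetic signal generators with ground
    truth, and simulation drivers that characterise estimator variance,
    settling time, buffer density dynamics, small-change ROC discrimination and
    outlier robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
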