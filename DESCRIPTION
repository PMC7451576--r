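Package: svperf
Title: Somatic Structural Variant Detection Performance: Benchmarking,
    Surface Modelling and Study Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarks somatic structural variant (SV) callsets against
    truth sets under a breakpoint-precision threshold, derives pairwise
    union and intersection callsets under the dominant-caller convention,
    generates synthetic truth sets on a masked genome and emulates caller
    outputs with known detection, breakpoint-jitter and false-positive
    behaviour, fits smooth additive performance-surface models
    (sensitivity, precision, F1) over VAF x coverage x threshold grids
    using beta regression with tensor-product penalized smooths, selects
    among eight candidate model forms by leave-one-level-out
    cross-validation, and predicts detection performance with uncertainty
    and minimum-requirement tables for proposed study designs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    IRanges,
    GenomicRanges,
    rtracklayer,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
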