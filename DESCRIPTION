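Package: dimtrace
Title: Time-Resolved Decoding of Behavior-Derived Object Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links continuous, behavior-derived object dimensions to
    time-resolved multichannel neural recordings. Provides timepoint-wise
    ridge decoding and encoding models with session-wise and
    across-participant cross-validation, permutation-based significance
    testing with max-statistic correction across dimensions and timepoints,
    and dynamic-time-warping shape clustering of dimension time courses.
    Includes a synthetic-data generator that plants dimension-specific
    temporal response profiles (early transient, late sustained, and
    stimulus-offset components) in simulated sensor data so the full
    pipeline can be exercised and validated end to end without any
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
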