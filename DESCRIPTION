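Package: funcprofile
Title: Physical Function Profiles from Minute-Level Wearable Activity Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers physical function from free-living wearable
    activity-monitor data recorded as activity counts per minute. Implements
    nonwear detection and valid-day selection, divisive energy-statistic
    change-point segmentation of daily count sequences, pattern-class
    indexing of segments in mean-SD space, per-subject function profiles
    (average daily minutes per pattern class), and weighted
    ordered-categorical additive models that classify subjects into quartile
    bands of clinical physical-capacity measures (400-m walk time, 20-m walk
    pace, five-repetition sit-stand rate), evaluated by the Goodman-Kruskal
    Gamma rank correlation. Includes a synthetic cohort generator that
    emulates bout-structured accelerometer traces so the whole pipeline can
    be exercised without access-restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mgcv,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
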