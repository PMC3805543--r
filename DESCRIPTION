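Package: ppgpeaks
Title: Systolic Peak Detection in Photoplethysmogram Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects systolic peaks in single-channel photoplethysmogram (PPG)
    recordings. Implements an event-related dual moving-average detector with a
    dynamic offset threshold, alongside three widely used comparators (local
    extrema with an amplitude delta, a first-derivative delineator with
    adaptive thresholds, and a slope-sum detector with adaptive thresholding).
    Includes beat-detection evaluation statistics (sensitivity, positive
    predictivity, overall accuracy at a fixed match tolerance), brute-force
    grid-search parameter optimisation, and a ground-truthed synthetic PPG
    generator emulating resting and post-exercise heat-stress recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
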