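Package: microstates
Title: Resting-State EEG Microstate Segmentation and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state EEG microstate analysis: global field
    power (GFP) computation and peak detection, polarity-invariant modified
    K-means clustering of GFP-peak topographies into microstate classes,
    cross-subject template alignment by permutation maximisation of common
    variance, back-fitting of class labels with run segmentation into
    duration, occurrence and coverage profiles, transition-syntax (doublet
    and triplet) statistics, and the split-plot group-by-class statistical
    layer with post-hoc t-tests and Spearman severity correlations. Includes
    a synthetic multichannel EEG cohort generator with planted prototype
    topographies and group effects so the full pipeline is testable without
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
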