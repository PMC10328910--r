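Package: nucleoprog
Title: Nuclear Morphometry and Spatial Heterogeneity for Tumor Recurrence Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative nuclear morphometry pipeline for predicting
    postoperative recurrence of clear cell renal cell carcinoma from
    histology regions of interest (ROIs). Extracts an 80-feature
    size/shape, Haralick chromatin-texture and radial-distribution
    profile per nucleus, aggregates nuclei to 960-feature ROI vectors
    with cell-feature-level co-occurrence matrices (CFLCM) capturing
    spatial heterogeneity, trains horizon-specific (5- and 10-year)
    linear support vector machine classifiers with ROI-to-case
    probability averaging, and combines the two horizons into a
    quadrant classification of recurrence timing. Includes seeded
    synthetic nuclei-image and cohort generators so the full pipeline
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
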