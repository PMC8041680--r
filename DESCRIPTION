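Package: visearch
Title: Visual-Search Eye-Movement Analysis with Scanpath Recurrence and
    MultiMatch Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cued visual-search eye-tracking experiments:
    dispersion-threshold (I-DT) fixation detection from raw gaze samples,
    area-of-interest labelling and rule-based trial segmentation into encoding
    and search phases, per-trial oculomotor variables with per-participant mean
    (performance) and standard-deviation (intra-subject variability) summaries,
    categorical Recurrence Quantification Analysis of search scanpaths,
    MultiMatch five-dimension scanpath similarity over same-target trial pairs,
    and a group-comparison layer (one-way ANOVA, Tukey post hoc with effect
    sizes, covariate-adjusted ANCOVA, within-group outlier screening).  A
    synthetic gaze-trial generator with full ground truth makes every stage
    testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
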