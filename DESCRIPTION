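Package: lexrsa
Title: Representational Similarity Analysis of Word-Reading Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representational similarity analysis (RSA) of
    word-reading multi-voxel patterns. Builds theoretical dissimilarity
    matrices for word stimuli (weighted Levenshtein orthographic distance,
    embedding-based semantic distance, lexical-frequency and word-length
    confounds), estimates condition patterns from event-related time series
    with a canonical-HRF general linear model, computes cross-validated
    Euclidean neural dissimilarity matrices across runs, and relates neural
    to theoretical geometry through confound-partialled Spearman
    correlations with signed-rank group inference, false-discovery-rate
    control, and factorial models. Includes a synthetic-data generator that
    plants a known semantic/orthographic mixture geometry in simulated
    patterns or BOLD series so the full pipeline can be calibrated and
    power-tested, plus behavioral summary statistics (efficiency scores,
    reaction-time trimming, effect sizes, mixed repetition ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
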