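Package: decodersa
Title: Time-Resolved Decoding RDMs and Cross-Modal Representational
    Similarity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds time-resolved neural representational dissimilarity
    matrices (RDMs) from multichannel trial data by pairwise
    cross-validated linear support-vector-machine decoding, constructs
    hypothesis RDMs for object real-world size, retinal size and inferred
    real-world depth, and compares them with full and partial Spearman
    representational similarity analysis. Inference tools include
    sign-flip cluster-based permutation tests over timecourses,
    bootstrap peak-latency estimation by resampling RDM cells,
    shuffle-null tests for model-feature RDMs, commonality-analysis
    variance partitioning, and leave-one-subject-out noise ceilings. A
    synthetic-data generator injects known time-localized feature
    geometry into simulated recordings so the whole pipeline can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
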