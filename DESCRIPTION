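Package: tdpatterns
Title: Temporal Dietary Pattern Discovery and Validation from 24-Hour Recalls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discovers temporal dietary patterns (TDPs) from event-level
    24-hour dietary recall data and validates descriptive energy/time
    cut-off rules against them. Implements a modified dynamic time warping
    (MDTW) distance over eating-event sequences with a configurable
    time-penalty weight, kernel k-means clustering on the resulting
    distance matrix with silhouette and Dunn validity indices, a rule-based
    energy/time cut-off classifier, cluster-membership overlap validation
    via optimal label assignment, and survey-weighted linear models
    (Taylor-linearized variances over strata and primary sampling units)
    relating pattern membership to body mass index and waist circumference
    with Tukey-Kramer-adjusted pairwise contrasts. A synthetic dietary
    recall generator emulating archetypal eating patterns, survey design,
    and outcome effects makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    jsonlite,
    mclust,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
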