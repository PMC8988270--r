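Package: symptomnet
Title: Regularized Partial-Correlation Networks of Depressive Symptoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and comparison of regularized partial-correlation
    networks of questionnaire symptom data, as used in psychopathology
    network studies of depression. Provides covariate residualization of
    ordinal item scores, graphical-LASSO estimation with extended-BIC
    penalty selection, weighted-graph centrality indices (strength,
    closeness, betweenness), permutation-based network comparison tests,
    chi-square tests on nonzero-edge ratios with Holm correction,
    nonparametric bootstrap edge-weight confidence intervals, case-dropping
    centrality stability with the CS-coefficient, and a synthetic-cohort
    generator with known conditional-independence ground truth for testing
    the full pipeline without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    MASS,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
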