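Package: geme
Title: Complexity of Weighted Networks via Graph Embedding and Point Pattern Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the complexity and non-randomness of dense weighted
    networks (for example functional brain connectivity matrices) by
    projecting the network into a low-dimensional Euclidean space through a
    double-centered Gram factorization and quantifying the deviation of the
    resulting point pattern from complete spatial randomness with an
    edge-corrected Ripley's K estimator.  The integrated curve yields a
    single permutation-invariant complexity score ('Geme').  Includes a
    block-covariance simulator for groups of correlation networks,
    Monte-Carlo power analysis for two-group comparisons, and covariate
    regression utilities for synthetic cohorts.
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
    optparse,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
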