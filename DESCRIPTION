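Package: dasnet
Title: Spectral Desynchronization Scoring and Post-Surgery Connectome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency-domain analysis of resting-state BOLD signals
    (total, binned and cumulative spectral power, and a signed Dynamics
    Alteration Score between two signals), functional-network richness and
    similarity scores, lesioned-connectome assembly rules (streamline
    budgets, greedy matrix merging, log-weight normalization, power-law
    tail diagnostics), and a prior-guided one-hidden-layer neural
    predictor of post-surgery structural connectomes benchmarked against
    Huber and null regressors under leave-one-out cross-validation.
    Includes a synthetic cohort generator with known spectral and
    surgical ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    pracma,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
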