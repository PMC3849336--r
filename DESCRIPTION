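Package: synergynet
Title: Synergy-Network Feature Ranking for Case-Control Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies prognostic biomarkers in case-control data by ranking
    features on a synergy network: node weights encode individual predictive
    power (-log p of a single-variable logistic coefficient) and edge weights
    encode pairwise synergistic power (-log p of a logistic interaction
    coefficient). Feature ranking is obtained from the leading eigenvector of
    the synergy matrix, a spectral relaxation of a size-constrained maximum
    weighted clique objective, and is combined with forward feature selection
    under an embedded (leakage-free) ten-fold cross-validation protocol with a
    quadratic discriminant analysis classifier. Includes an exact subnetwork
    solver for small instances, a mixture-of-Gaussian case-control simulator
    with sparse pairwise logistic interactions, consensus biomarker extraction
    from repeated cross-validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    xml2,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
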