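Package: l0em
Title: L0-Penalized Regression via EM Fixed-Point Iteration and Sparse
    Network Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Best-subset (L0-penalized) linear regression solved by an EM
    fixed-point iteration that reduces the combinatorial problem to a short
    sequence of reweighted ridge solves (L0EM), with an equivalent dual form
    (DL0EM) for high-dimensional n << m data and a generalization to Lp
    penalties, p in [0,2], covering ridge and the lasso.  Includes
    regularization-parameter selection by k-fold cross-validation,
    stability selection, their combination, and AIC/BIC/RIC rules;
    regularization paths; a neighborhood-selection Gaussian graphical model
    for coexpression-network construction with structure-recovery metrics
    (AUC, edge FDR/FNR); seeded simulation generators for AR(1) designs and
    banded-precision network data; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    tools,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
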