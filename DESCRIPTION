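Package: contactsol
Title: Protein Solubility Regression with Graph Convolutional Networks on
    Predicted Contact Maps
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts continuous protein solubility (the eSOL definition:
    supernatant fraction over total fraction, in [0,1]) from sequence-derived
    residue features and a predicted residue-residue contact map.  Proteins
    are represented as attributed graphs whose nodes carry BLOSUM62,
    physicochemical, PSSM, HMM-profile and predicted-structure features and
    whose weighted edges come from contact probabilities (full map or the
    top alpha*L pairs, continuous or discrete weights).  A degree-normalized
    graph convolutional network with multi-head self-attention pooling and a
    sigmoid head performs the regression; training (Adam on mean squared
    error), k-fold cross-validation over repeated seeds, ensemble averaging
    and the full metric suite (RMSE, R-squared, threshold classification,
    AUC) are included, together with parsers for PSI-BLAST PSSM, HH-suite
    .hhm and SPIDER3 .spd33 profile files, contact-map readers, Calpha
    contact evaluation against structures, and a synthetic-data generator
    that makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Biostrings,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
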