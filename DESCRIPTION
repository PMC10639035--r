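Package: oripredict
Title: Cell-Specific Prediction of DNA Replication Origins from Sequence Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts origin-of-replication (ORI) windows in eukaryotic DNA from
    fixed-length sequence windows. Fuses three classical sequence encodings --
    composition of k-spaced nucleic acid pairs (CKSNAP), parallel-correlation
    pseudo dinucleotide composition (PCPseDNC), and dinucleotide cross covariance
    (DCC) over a physicochemical index table -- with features from a convolutional
    / bidirectional-GRU / attention neural descriptor, selects features by Shapley
    attributions on a gradient-boosted tree model, and classifies with a boosted
    tree ensemble. Includes a synthetic benchmark generator with plantable motif
    and GC-skew signals, stratified cross-validation, an independent-test
    evaluation suite, cross-cell generalization matrices, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    xgboost,
    jsonlite,
    Biostrings,
    optparse,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
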