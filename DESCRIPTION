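Package: hdselect
Title: Hyperdimensional Computing Classification and Backward Feature
    Elimination for Microbial Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification of case/control microbial profiles with a
    vector-symbolic architecture (hyperdimensional computing): numeric values
    are quantized into quasi-orthogonal bipolar level hypervectors, samples
    are encoded by feature-wise rotation and bundling, and classes are
    represented by accumulated class hypervectors refined by an iterative
    retraining (error mitigation) step. On top of the classifier, a stepwise
    backward variable elimination wrapper selects discriminative species
    under cross-validated accuracy with an uncertainty band, and tracks the
    sub-optimal model with the fewest features above an accuracy floor.
    Includes MetaPhlAn-style relative-abundance table readers, multi-study
    harmonization, abundance/prevalence filters, binarization, sex/age
    stratification, prevalence/log2 fold-change/Wilcoxon-BH differential
    abundance statistics, and a synthetic case/control profile generator
    with planted discriminative species.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
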