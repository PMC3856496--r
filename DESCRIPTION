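Package: TriTV
Title: Tricluster Detection in Gene x Condition x Time Tensors by
    Total-Variation Regularized Tensor Factorization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects gene x condition x time modules (triclusters) from
    dense third-order time-series expression tensors. Fits a rank-K
    CP/PARAFAC-style factorization whose time factor carries a total
    variation penalty, solved by alternating least squares with an ADMM
    inner loop for the time mode, so that discovered modules occupy
    consecutive time intervals. Includes module extraction by per-column
    sign correction and thresholding, a planted-module synthetic
    benchmark generator, Fscore/NMI evaluation against ground truth,
    long-format TSV tensor input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    igraph,
    data.table,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
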