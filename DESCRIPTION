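Package: deepIDA
Title: Deep Integrative Discriminant Analysis for Multi-View Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint nonlinear association and discrimination for two or more
    row-aligned data views (e.g. proteomics, metabolomics, RNA-seq measured on
    the same samples). Per-view feed-forward networks are trained to maximize
    the sum of the leading eigenvalues of a whitened between-class plus
    cross-view association operator, combining linear discriminant analysis
    and canonical correlation ideas in one eigensystem objective. Includes
    nearest-centroid classification on the learned representations, a
    bi-bootstrap permutation framework that ranks features by how often
    permuting them degrades out-of-bag classification, and a nonlinear
    two-view simulation generator with ground-truth signal masks for method
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
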