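Package: ipcarf
Title: Predicting lncRNA-Disease Associations with IPCA and Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts associations between long noncoding RNAs (lncRNAs) and
    diseases from a known association catalogue. Disease-disease similarity is
    computed from a disease ontology (directed acyclic graph) with two semantic
    models (contribution-decay and information-content), lncRNA and disease
    similarities are computed with Gaussian interaction profile kernels on the
    association matrix, and the similarity matrices are integrated into one
    feature vector per lncRNA-disease pair. Features are reduced with a
    covariance column-selection variant of principal component analysis (IPCA:
    top column norms, QR orthonormalisation, singular value decomposition of
    the compressed covariance) and classified with a random forest. Includes
    stratified k-fold cross-validation with accuracy, precision, recall, F1,
    ROC and AUC reporting, a grid search over the forest size, per-disease
    candidate ranking, a planted-block synthetic data generator for end-to-end
    benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
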