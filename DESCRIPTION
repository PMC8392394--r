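Package: hairpinSVM
Title: Plant Pre-miRNA Hairpin Classification with Knowledge-Based
    Energy Features and Support Vector Machines
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies plant microRNA precursor (pre-miRNA) hairpins
    among candidate RNA sequences. Implements a 193-dimensional feature
    representation combining knowledge-based k-mer pair pseudo-energies
    (position-specific, distance-specific and distance-dependent
    Boltzmann-inverted potentials trained from positive and pseudo-hairpin
    sequence sets), secondary-structure element statistics (stems, loops,
    bulges, pairing counts), thermodynamic ratios and k-mer composition.
    Includes pseudo-hairpin negative-set construction from coding
    sequence, z-score normalization with scaler persistence, RBF-kernel
    support vector machine training with grid search, stratified k-fold
    cross-validation, ROC/AUC and top-N consistency evaluation, a
    Nussinov-style base-pair-maximization folding fallback, and seeded
    synthetic data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
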