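Package: raaclass
Title: Protein Family Classification with Reduced Amino Acid Alphabets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies labeled protein sequence families from n-peptide
    (k-mer) composition over reduced amino acid alphabets derived from the
    protein blocks structural alphabet. Provides the built-in cluster
    profiles CP(20)/CP(13)/CP(11)/CP(9)/CP(8)/CP(5), composition feature
    extraction for word lengths 1-3, an RBF-kernel support vector machine
    with one-vs-one multiclass decomposition and grid-searched
    hyperparameters, Random Forest and Naive Bayes baselines, jackknife and
    stratified k-fold cross-validation with per-class sensitivity,
    specificity and Matthews correlation coefficient, per-residue
    composition comparison by one-way ANOVA with Fisher's LSD post hoc
    test, binomial over-representation tests for reduced n-peptides, and a
    seeded synthetic sequence generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    randomForest,
    jsonlite,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
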