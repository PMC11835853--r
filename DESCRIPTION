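Package: mnapred
Title: Missense Pathogenicity Prediction from Peptide Molecular Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the pathogenicity of single amino-acid substitutions
    by representing the peptide window around the substituted residue as a
    molecular graph, describing it with canonical Multilevel Neighborhoods
    of Atoms (MNA) descriptors, and classifying the descriptor set with a
    PASS-style naive-Bayes model reporting Pa, Pi and Confidence = Pa - Pi.
    Includes MDL SD file input/output, Invariant Accuracy of Prediction
    (ROC AUC) under leave-one-out and stratified k-fold cross-validation,
    grid selection over peptide length and descriptor level, ClinVar- and
    gnomAD-style variant curation rules, a synthetic-data generator, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ChemmineR
Config/testthat/edition: 3
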