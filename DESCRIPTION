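Package: cppscreen
Title: Screening for Cell-Penetrating Peptides with PUK-Kernel Support Vector Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification and in-silico screening of cell-penetrating peptides
    (CPPs). Computes a fixed panel of 61 primary biochemical descriptors for
    peptide sequences, builds training sets under five class-imbalance
    strategies, trains support vector machines with the Pearson VII universal
    kernel by sequential minimal optimization, performs scatter-search wrapper
    feature selection with cross-validated accuracy as the objective, and
    screens candidate peptides generated from a 0th-order Markov model of
    amino-acid composition. Bundles the compiled sets of 111 known CPPs, 34
    known non-penetrating analogs, and 13 experimentally validated peptides.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, jsonlite, seqinr, stats, utils, tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, kernlab, pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
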