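Package: immunograph
Title: Graph Attention Modeling of Peptide-HLA Immunogenicity and
    Neoantigen Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for T-cell neoantigen discovery built around a graph
    attention network that scores the immunogenicity of peptide-HLA class I
    complexes. Amino acids are embedded with principal components of
    robustly normalized AAindex1 physicochemical indices; each peptide and
    the 34-residue HLA pseudo-sequence become nodes of a fully connected
    graph with a virtual readout node, classified by three rounds of
    multi-head attention message passing with per-graph feature
    normalization. The package also implements assay-evidence curation
    rules for epitope training data, peptide similarity search by global
    alignment, mutant/wild-type peptide window extraction from missense
    mutations, the differential agretopicity index, and a multi-feature
    neoantigen filtering cascade with a pluggable predictor contract, plus
    classification metrics (sensitivity, F1, TopK, ROC/AUC) and seeded
    synthetic-data generators for every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
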