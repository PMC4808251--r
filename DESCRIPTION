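Package: cidrex
Title: Chemical-Induced Disease Relation Extraction from Biomedical Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for extracting chemical-induced disease
    (CID) relations from PubMed-style abstracts in PubTator format. Chemical
    and disease mentions are recognized with linear-chain conditional random
    fields over lexical, orthographic, dictionary, affix and word-embedding
    features; mentions are normalized to MeSH identifiers by TF-IDF cosine
    similarity in a term vector space; document-level CID relations are
    classified by a sentence-level and a document-level linear SVM whose
    positive predictions are combined by union. Includes MeSH tree-number
    algebra, knowledge-base (CTD/SIDER/MEDI) feature lookups, the standard
    mention-, concept- and relation-level evaluation metrics, and a seeded
    synthetic-fixture generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    e1071,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
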