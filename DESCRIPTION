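Package: mimovar
Title: Mimotope Variation Analysis of Phage-Display Immunoprofiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for next-generation phage-display mimotope
    variation analysis (MVA) immunoprofiles. Starting from per-subject
    12-mer peptide count tables, the package discovers enriched wildcard
    sequence motifs by an exhaustive trie search with hypergeometric
    scoring, filters group-differentiating motifs, aligns motifs to
    bacterial proteomes and scores tiled 20-amino-acid fragments by
    alignment load, clusters aligned substrings into position-weight-matrix
    target types, groups differential motifs into homology clusters and
    correlation-defined epitope groups, computes per-subject antigen
    alignment profiles against a scrambled-peptide null, and fits a
    two-step epitope-biomarker classifier (logistic periodontitis model
    plus per-stratum ROC thresholds for acute coronary syndrome risk).
    A synthetic-cohort generator with recorded ground truth supports
    end-to-end validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
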