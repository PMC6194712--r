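Package: cofracgold
Title: Benchmarking Gold-Standard Protein Complexes Against Co-Fractionation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates literature-curated protein-complex databases (CORUM-style
    complex tables and pairwise interactomes) against co-fractionation
    chromatogram data. Computes pairwise profile similarity (zero-filled Pearson
    correlation, min-max-normalized Euclidean distance), complex-level
    permutation statistics with Benjamini-Hochberg correction, hypergeometric
    enrichment of published interactome edges within complexes,
    technique-specific complex selection with a bootstrap chance model,
    derivation of co-fractionation-specific gold-standard subsets, Gini-based
    tissue-expression consistency analysis, and a Gaussian Naive Bayes
    interactome predictor evaluated by precision-recall and interactome size at
    fixed precision. Includes seeded synthetic-data generators for every input
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
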