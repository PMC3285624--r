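Package: drpan
Title: Pan-Specific HLA-DR Peptide Binding Prediction by Pocket PSSM
    Extrapolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extrapolates position-specific scoring matrices (PSSMs) for
    arbitrary HLA-DR alleles from a small library of experimentally
    characterized pocket specificity vectors.  Each of the nine binding
    pockets of an allele is represented by a pseudosequence of contact
    residues; pocket-level similarity between a query allele and the
    library alleles is measured with BLOSUM62 and converted to convex
    weights, and the query's specificity vector for every pocket is the
    weighted average of the library vectors.  Includes peptide scanning
    with 9-mer binding-core identification, binding-motif sampling for
    sequence logos, an evaluation harness (ROC AUC, exact one-tailed
    binomial tests, exact-core error counting), derivation of pocket
    contact positions from MHC-peptide complex structures, and synthetic
    fixture generators so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
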