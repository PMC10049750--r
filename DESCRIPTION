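Package: polyphylo
Title: Phylogenomic Supermatrix Construction and Ancestral State
    Reconstruction for Flatworm Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building phylogenomic data matrices from
    transcriptome-derived protein sequences and for reconstructing the
    evolution of discrete life-history traits on the resulting trees.
    Implements construction of clade-specific BLOSUM-style log-odds
    amino-acid substitution matrices from conserved gap-free alignment
    blocks, orthology assignment with E-value and top-quartile hit
    filtering plus reciprocal-best-hit confirmation under a custom
    scoring matrix, out-paralog pruning by maximally inclusive subtree
    selection with in-paralog consensus, codon-aware supermatrix
    concatenation with occupancy and codon-column filters, and
    maximum-likelihood fitting of two-state Mk models (equal-rates and
    all-rates-different) with AICc model selection, marginal ancestral
    "scaled likelihoods" and proportional-likelihood significance
    calls.  A synthetic-data module generates clusters, gene families
    with paralogs, transcript fragments and binary traits with known
    ground truth so that every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
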