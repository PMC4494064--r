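Package: paleozyme
Title: Gene-Family Reconciliation, Phylogenetic Signal, and
    Penalized-Likelihood Dating for Enzyme Family Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing the evolution of enzyme gene families
    across a dated species phylogeny. Implements duplication-loss
    parsimony reconciliation of gene trees against a species tree with
    weak-branch rearrangement, bootstrap averaging and ancestral
    copy-number reconstruction; penalized-likelihood divergence-time
    estimation with cross-validated rate smoothing and fixed-age
    calibrations; four-cluster likelihood mapping on a built-in pruning
    likelihood engine; random-addition concatenation curves with clade
    fixation points; single-copy ortholog filtering, supermatrix
    concatenation and Dayhoff recoding; and copy-number surveys of
    carbohydrate-active enzyme families from homology hit tables. A
    synthetic-data layer simulates every input with recorded ground
    truth: ultrametric species trees, birth-death gene families,
    relaxed-clock phylograms, amino-acid alignments, ortholog cluster
    tables and homology hit tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
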