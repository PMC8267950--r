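Package: mifishr
Title: Single-Cell miFISH Copy-Number Clonality, Phylogeny and Ploidy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multiplex interphase FISH (miFISH)
    copy-number profiling of tumor nuclei. Aggregates per-nucleus probe
    signal patterns into clones, annotates per-nucleus and sample ploidy,
    calls gains, losses and amplifications relative to ploidy, computes the
    instability index of intratumor heterogeneity, builds single-step clone
    graphs and minimal-event copy-number phylogenies with inferred transit
    nodes and whole-genome-duplication edges, runs margin-preserving
    permutation tests for mutual exclusivity and co-occurrence of
    alterations with Benjamini-Hochberg correction, applies a hard-filter
    cascade to annotated somatic variant calls, classifies DNA-content
    image-cytometry histograms as diploid or aneuploid, and simulates
    synthetic nucleus tables, variant tables and histograms with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
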