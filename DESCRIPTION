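Package: pepgo
Title: Peptide-Centric Metaproteomics with Gene Ontology Spectral Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for peptide-centric metaproteomics of microbial
    communities. Quantifies Gene Ontology (GO) functions by propagating
    peptide spectral counts to annotated terms and all their ancestors in
    the GO directed acyclic graph, assigns each peptide a lowest common
    ancestor (LCA) taxon with class-level rollup and an Unclassified sink,
    tests for functional enrichment between mass-spectrometry runs with
    Laplace-corrected log2 fold changes and a Bonferroni-controlled
    two-tailed test of proportions restricted to terminal GO terms,
    compares functional versus taxonomic per-day rates of change by a
    row-level permutation test, and measures concordance between
    peptide-derived and 16S rRNA class abundances. A synthetic-data
    generator emulates time-course incubation experiments with spiked
    functional effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
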