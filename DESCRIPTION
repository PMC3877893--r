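Package: cyanoscreen
Title: PCR-Based Screening and Phylogenetics of Cyanobactin Protease Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of a PCR-based screen for cyanobactin
    N-terminal protease (A) genes in cyanobacteria: degenerate primer design from
    nucleotide alignments, in-silico PCR with IUPAC semantics, k-mer discrimination
    of the homologous A and G protease genes, maximum-likelihood phylogenetics under
    the Kimura 2-parameter model with discrete-gamma rate variation and invariant
    sites (K2P+G+I) including nonparametric bootstrap support, and gene-tree versus
    16S-tree incongruence analysis that flags novel clades and lateral-transfer
    candidates. A seeded synthetic-data generator produces species trees, HGT-bearing
    gene trees, evolved sequences with implanted primer sites, and diverged G-gene
    paralog families with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phytools,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
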