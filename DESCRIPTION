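Package: AncestralGenomics
Title: Macro-Synteny, Methylation Signatures, Sex-Linked Scaffolds and
    Ancestral Gene Content
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analyses for detecting conservative genome
    evolution in a newly assembled genome: enrichment of scaffolds for
    ancestral linkage groups by one-sided Fisher's exact tests with
    Bonferroni correction, CpG observed/expected dinucleotide profiling
    of gene bodies and genome windows with univariate Gaussian mixture
    decomposition of methylation signatures, read-depth based
    classification of X-linked, Y-derived and autosomal scaffolds from
    male and female sequencing, and Dollo-parsimony reconstruction of
    ancestral gene-family content with per-branch gains and losses.
    Ground-truthed synthetic data generators make every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    ape,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ComparativeGenomics, Phylogenetics, DNAMethylation, Coverage
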