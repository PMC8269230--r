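Package: virolink
Title: Host-Virus Linkage and Paired Community Analysis for Soil Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds viral population catalogues from predicted viral scaffolds
    (length filtering, greedy dereplication at 99 percent identity, merging of
    upstream lysogeny and completeness calls), computes breadth-filtered and
    depth-normalized abundances from read alignments, recovers CRISPR spacers
    directly from unassembled reads given per-genome direct repeats, and
    predicts host-virus interactions through four sequence-based evidence
    channels: spacer-to-protospacer matching, alignment-free d2* oligonucleotide
    frequency dissimilarity, exact tRNA sharing, and nucleotide homology.
    Evidence is integrated into an interaction network with per-virus host
    counts.  Paired virome/microbiome community statistics include
    Shannon-Wiener diversity and Pielou evenness, Bray-Curtis distances, PCoA,
    PERMANOVA, BioENV environmental subset search, and symmetric
    co-correspondence analysis.  A seeded synthetic desert-soil community
    generator with planted, machine-readable ground truth (CRISPR arrays,
    protospacers with controlled mutations, shared tRNAs, embedded prophages,
    composition-coupled virus-host pairs, error-bearing reads, multi-site
    abundance matrices) makes the whole pipeline testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    vegan,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
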