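Package: peakcontext
Title: Genomic-Context Categorisation and Statistical Comparison of Locus Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates genomic loci (e.g. ChIP-seq peaks) with their context
    relative to gene models by partitioning every base of the genome into one
    of seven exhaustive, mutually exclusive categories (exon, intron, 5' near,
    3' near, 5' far, 3' far, distant), reports nearest genes with signed
    strand-aware distances to gene 5' and 3' ends, and statistically compares
    the category distributions of two locus sets using the Brandt-Snedecor
    chi-square test of homogeneity together with per-category log-likelihood
    G-tests. Also provides distance histograms, TSS-in-window counts, element
    track overlaps (e.g. CpG islands), reference sequence retrieval,
    term-for-term GO over-representation of nearest genes, SVG reports, a
    seeded synthetic annotation and locus generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
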