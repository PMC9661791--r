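Package: contigMend
Title: Reference-Free Identification and Correction of Misassembled
    Contigs in Metagenomic Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects structural misassemblies (inter-genome translocations,
    relocations, inversions) in de novo (meta)genomic assemblies without
    reference genomes, using features extracted from the alignment of
    paired-end reads to contigs: read-pair consistency, standardized read and
    fragment coverage, per-base nucleotide variants, and the k-mer abundance
    difference (KAD) statistic. Misassembled contigs are scored by a
    down-sampled random-forest ensemble, breakpoints are localized with an
    isolation forest over 100-bp window features combined with read-breakpoint
    ratios, and misassemblies are corrected by splitting contigs at
    breakpoints. Includes a truth-labelled synthetic community and chimeric
    read simulator, and evaluation metrics for classification, breakpoint
    error, and binning quality.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    ranger,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
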