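Package: selkie
Title: Coverage, Heterozygosity, Synteny and Assembly Diagnostics for
    Chromosome-Length Pinniped Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for chromosome-length mammalian genome
    assemblies, motivated by comparative pinniped genomics. Implements
    coverage-based sex verification and pseudoautosomal-region (PAR)
    detection from windowed read-depth medians via a two-pass segment
    merging rule, ploidy-aware variant filtering with per-rule removal
    accounting, sliding-window heterozygosity densities and their
    summaries, synteny-block filtering with chromosome correspondence
    assignment and inversion calling, and assembly summary statistics
    (N50/L50, chromosome-scaffold cutoff detection, BUSCO percentage
    conversion, k-mer spectrum genome-size estimation). A seeded
    synthetic-data generator produces depth tracks, VCFs, synteny block
    sets and k-mer histograms with planted ground truth so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    GenomicRanges
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: GenomeAssembly, Coverage, SNP, Software
RoxygenNote: 7.3.3
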