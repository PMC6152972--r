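Package: mirnaforge
Title: Small-RNA miRNA Discovery, Arm-Usage Profiling and Comparative
    Genomics for Insect Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for discovering novel microRNA loci
    from small-RNA sequencing reads and characterizing them across genomes.
    Implements hairpin-based locus calling from collapsed read stacks
    (pair-maximizing secondary-structure folding with duplex-geometry
    validation), arm-usage and arm-switching analysis, 5'-isomiR fidelity
    profiling, sex-biased differential expression via an exact binomial
    count test, seed-and-energy consensus target prediction, word-seeded
    cross-genome homolog search with flank-extended hairpin validation,
    and genomic miRNA-cluster detection. Ships a synthetic-data generator
    that plants pre-miRNA hairpins into simulated genomes and emits read
    libraries with controlled arm bias, 5' jitter, star-read frequencies
    and sex-biased abundances, with full truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
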