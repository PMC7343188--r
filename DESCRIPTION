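Package: arthromethyl
Title: Comparative CpG Methylome Analysis for Arthropod Genomes
Version: 0.1.0
Authors@R: person("Methylome", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for comparative whole-genome bisulfite
    methylome analysis across arthropod species: per-CpG site filtering and
    genome-wide methylation summaries with spike-in based non-conversion
    estimation, feature-level methylation means with bootstrap confidence
    intervals and high/low mixture clustering, metagene profiles, detection
    of nucleosome-length periodicity in the distance-correlation of CpG
    methylation by Fourier analysis, maximum-likelihood Brownian-motion
    ancestral state reconstruction and phylogenetic generalized least
    squares, expression/methylation coupling (FPKM, tissue coefficient of
    variation, housekeeping enrichment, orthogroup summaries), and CAGE tag
    clustering with interquantile promoter widths plus nucleosome occupancy
    metagenes. A fully seeded synthetic-data generator emulates annotated
    multi-contig genomes, class-specific methylation architectures,
    nucleosome-phased methylomes, bisulfite counts with non-conversion
    error, Brownian traits on time trees, tissue-structured expression and
    CTSS/occupancy tracks, so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
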