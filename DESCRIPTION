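Package: sweepqtl
Title: Selective Sweep Scans and QTL Co-Localization for Crop Domestication
Version: 1.0.0
Authors@R:
    person(given = "Package", family = "Author", role = c("aut", "cre"),
           email = "author@example.org")
Description: Population-genomic detection of domestication targets in crops
    such as rice. Implements coalescent simulation of a two-population
    split-with-bottleneck model for partially selfing species (with an exact
    ancestral-recombination-graph engine and a star-approximation operator for
    completed selective sweeps), simulation-based composite-likelihood
    inference of the domestication bottleneck from per-gene synonymous
    diversity, simulation-null scoring (logP) of windowed diversity ratios
    (pi and Watterson's theta), windowed Hudson F_ST differentiation scans,
    co-localization of candidate regions with QTL intervals, and a screen for
    variants fixed in the cultivated population with replacement, frameshift
    or regulatory effects. A synthetic-data generator exports complete fake
    study datasets (FASTA/GFF3/VCF/QTL/popmap plus truth tables) for
    end-to-end validation against planted sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    methods,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
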