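Package: linkphase
Title: Simulation, Processing and Phasing of Targeted Linked-Read Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying haplotype phasing of targeted loci with
    microbead co-barcoded (linked-read) short-read sequencing. Provides a
    synthetic-data generator with known truth (diploid target loci, picogram
    mass to molecule-count conversion, Poisson bead loading with collisions,
    filling DNA, barcoded paired reads with sequencing and PCR artifacts), a
    processing chain (adapter trimming, bead-barcode error correction,
    within-barcode duplicate marking, lite k-mer read mapping, pileup
    genotyping with an allele-frequency cutoff, and barcode-linked
    minimum-error-correction phasing into phase blocks), and an evaluation
    suite (collision and linked-read efficiency metrics, on-target recovery,
    allele burden, switch/flip error decomposition, phase-block accounting,
    and sequencing-depth titration with phasing quality groups).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    yaml,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
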