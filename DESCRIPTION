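Package: tilepath
Title: Tiling Microarray Promoter Design and Sliding-Window ChIP Peak Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing genome tile-path ChIP-chip
    experiments on draft genome assemblies. Selects isothermal (melting
    temperature matched) oligonucleotide probes over repeat-masked genome
    sequence, detects enriched regions from per-probe log2(ChIP/input)
    ratios with a multi-window sliding-window scan whose thresholds are
    calibrated against randomized probe signals to a target theoretical
    false discovery rate, assembles an H3K4me3-driven promoter tile-path
    design under a probe budget, and annotates peaks: gene association,
    replicate correlation, transcription start site meta-profiles, overlap
    significance by permutation, and EST-based linkage of orphan promoter
    scaffolds to gene-body scaffolds. A self-contained simulator generates
    genomes, gene models, probe signals and split-scaffold ESTs with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
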