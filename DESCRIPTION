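Package: scidseq
Title: Single-Cell Immuno-Detection by Sequencing (scID-seq) Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes single-cell Immuno-Detection by sequencing (scID-seq)
    experiments, in which DNA-barcoded antibodies quantify dozens of
    (phospho-)proteins per FACS-sorted single cell. Covers the full
    computational workflow: demultiplexing antibody and well barcodes from
    FASTQ reads with Hamming-distance error correction, UMI-based molecule
    counting, empty-well background estimation, depth normalization by
    rarefaction, per-antibody min-max scaling, phospho/total ratios,
    marker-anchored PCA pseudo-time ordering with binned cubic trend fits,
    and two-sample Kolmogorov-Smirnov selection of dynamic epitopes between
    sorted populations. Includes a ground-truthed synthetic-data generator
    emulating plate-based scID-seq experiments (PCR duplication, sequencing
    errors, empty-well background, a latent differentiation trajectory) so
    the entire pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Matrix,
    Biostrings,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
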