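Package: nucleoshift
Title: Differential Nucleosome Position Calling from MNase Tiling-Array Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genotype-specific changes in nucleosome position from
    two-channel MNase tiling-microarray probe signals around gene
    transcription start sites. Implements the full analysis chain:
    a polymorphism filter that masks windows with divergent genomic-DNA
    hybridization between genetic backgrounds, a dual t-test region caller
    that labels gains and losses of positioned nucleosomes over runs of
    consecutive significant probes spanning at least 140 bp, classification
    of called regions by Pearson correlation against a sequence-intrinsic
    nucleosome occupancy likelihood (NOL) track, and MNase-qPCR / qRT-PCR
    relative quantification via the 2^-ddCt method. Ships a deterministic
    synthetic-data generator with recorded ground truth for calibration and
    benchmarking, plus readers and writers for the probe-signal GFF dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
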