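Package: widee
Title: Window-Based Detection of Differential A-to-I RNA Editing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects differential adenosine-to-inosine (A-to-I) RNA editing
    between two sets of aligned RNA-seq samples. Annotated regions are tiled
    into non-overlapping windows; per-sample editing signals (sums of
    per-position A-to-G mismatch ratios) are averaged within each sample set
    and differenced to give a per-window editing delta. Empirical q values
    for the focal mismatch class are estimated from the eleven remaining
    mismatch classes, which act as decoy null distributions, aggregated by
    their median and monotonized within each sign tail. Includes a BAM
    pileup front end, an optional allele-frequency SNP filter, a seeded
    synthetic-data generator with ground truth, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
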