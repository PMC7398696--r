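Package: silest
Title: Single-Cell and Chromatin Models of Heterochromatic Silencing
    Establishment
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generative models and likelihood machinery for studying how
    heterochromatic silencing is established at the silent mating-type loci
    of budding yeast.  Distinguishes gradual transcriptional tune-down from
    discrete ON-to-OFF switching in single-cell transcript counts
    (smRNA-FISH) via negative-binomial and zero-mixture likelihoods with
    parametric-bootstrap model comparison; models replication-coupled
    dilution and turnover kinetics of histone H3K79 methylation; implements
    MNase ChIP-seq mononucleosome size selection, coverage, and
    normalization to the non-heterochromatic genome-wide median with
    per-gene normalized densities; and performs standard-curve RT-qPCR
    quantification with reference-gene normalization.  A seeded
    synthetic-data generator produces every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
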