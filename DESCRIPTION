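Package: sonoquant
Title: Cavitation Spectra and Microglial Transcriptome Metrics for
    Scanning-Ultrasound Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for therapeutic scanning-ultrasound
    (SUS+MB) blood-brain-barrier opening studies.  Decomposes passive
    cavitation detector (PCD) recordings into higher-harmonic,
    ultraharmonic and broadband components and quantifies each band's
    per-pulse intensity via Parseval's theorem; partitions
    differential-expression tables into up/down-regulated and
    contrast-shared gene sets with top-N ranking; performs hypergeometric
    gene-set over-representation tests; and quantifies hemisphere
    fluorescence fold-change for dye-extravasation assays.  Seedable
    synthetic generators emulate pulse trains with controlled harmonic,
    ultraharmonic and broadband content, DEG tables with planted
    partition structure, and paired hemisphere intensities, so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
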