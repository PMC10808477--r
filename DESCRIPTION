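Package: masscnv
Title: Semi-Quantitative CNV Calling from MALDI-TOF Peak Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Copy-number variant (CNV) calling for exon-level deletions and
    duplications in BRCA1/BRCA2-style multiplex MALDI-TOF (iPLEX single-base
    extension) dosage assays. Computes competitor-normalised Target Ratio
    (TR) values with reference-gene double calibration, applies cutoff-based
    deletion/duplication calls, merges per-fragment calls into exon-range
    events, calibrates cutoffs from control samples, simulates multiplexed
    intensity tables with known copy-number truth (including allele-dropout
    artifacts from SNVs under primer binding sites), scores calls against
    truth with diagnostic sensitivity/specificity, and characterises
    deletion breakpoints (HGVS g. parsing, junction microhomology,
    NAHR/NHEJ/MMEJ mechanism classification, repeat annotation, primer SNP
    screening).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    purrr,
    rlang,
    stringr,
    tidyr,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
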