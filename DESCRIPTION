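Package: umimrd
Title: Barcode-Consensus Variant Calling and Circulating Tumor DNA
    Recurrence Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Error-suppressed detection of low-frequency somatic variants
    in amplicon sequencing libraries tagged with 12-nt molecular barcodes
    (UMIs), and longitudinal circulating tumor DNA (ctDNA) monitoring of
    cancer patients after curative therapy.  Provides a barcoded-read
    simulator with explicit PCR and sequencing error processes, barcode
    family grouping and consensus calling with family-size-dependent
    agreement thresholds, per-base consensus pileups with minor allele
    frequencies, patient-specific mutation panel design from tumor
    variant calls, plasma sample positivity classification against a
    background noise model, and per-patient recurrence timelines with
    lead-time estimation.
License: MIT + file LICENSE
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
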