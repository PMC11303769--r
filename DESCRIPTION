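Package: enamelLFQ
Title: Label-Free Peptidomic Sex Determination from Tooth Enamel
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Targeted MS1 label-free quantification of sex-diagnostic
    amelogenin (AmelX/AmelY) peptides in LC-MS/MS runs of tooth enamel.
    Computes exact peptide masses, theoretical isotopic envelopes and b/y
    fragment ions; extracts and integrates extracted-ion chromatograms for a
    four-peptide marker panel; validates identifications by isotope-envelope
    similarity and MS2 fragment matching; estimates bulk Asn/Gln deamidation
    occupancy as a diagenesis check; and emits a male/female/indeterminate
    call per sample. Includes a deterministic DDA run simulator with ground
    truth so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    mzR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
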