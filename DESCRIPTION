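Package: arpmap
Title: Identification and Quantitation of ARP-Derivatized Carbonylated Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for mapping protein carbonylation sites from
    bottom-up LC-MS/MS data after aldehyde-reactive-probe (ARP) derivatization
    and biotin-avidin enrichment. Provides a registry of ARP-carbonyl adduct
    mass shifts with their diagnostic reporter-ion and neutral-loss profiles,
    in-silico tryptic digestion with pseudo-reversed decoys, reporter-ion
    spectrum triage, peptide-spectrum matching with tag-specific losses and
    target-decoy false discovery rate control, a six-criterion confidence
    classification of proposed ARP peptides, extracted-ion-chromatogram
    quantitation with recovery and enrichment summaries, and a ground-truth
    synthetic data generator (mzML/MGF/FASTA) for validating every stage
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    mzR,
    jsonlite,
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
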