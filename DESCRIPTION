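Package: haplopept
Title: Haplotype-Aware Proteogenomic Search Spaces and PSM Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the consequences of protein haplotypes on
    bottom-up proteomics. Builds search spaces of protein haplotype sequences
    from reference proteins and phased amino acid substitution sets, performs
    in silico tryptic digestion with missed cleavages, classifies peptides by
    variant content (canonical, single-variant, multivariant with downgrade
    rules) and by specificity (nonspecific, protein-specific,
    proteoform-specific), quantifies residue-level proteome coverage and
    substitution discoverability, generates collision-free decoy databases,
    and scores peptide-spectrum matches with spectrum angular similarity,
    calibrated retention-time deviation and target-decoy q-values. A
    synthetic-data generator with a ground-truth manifest makes the whole
    pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
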