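Package: cryoclean
Title: Background-Control Decontamination of Low-Biomass Amplicon Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contamination monitoring for low-biomass 16S rRNA amplicon
    studies of ice and water, built around two kinds of background controls:
    a processing control (an artificial sterile ice core handled alongside
    the samples) and a DNA-extraction control (a blank filter carried through
    extraction). Curates OTU count tables (domain-unclassified, eukaryote,
    organelle and singleton removal), identifies contaminant OTUs from the
    controls with per-control provenance and the PC-DC subtraction, applies
    four in-silico decontamination strategies with full removal ledgers, and
    produces the descriptive outputs such studies report: relative
    abundances, contaminant-load statistics, Venn set partitions, taxonomic
    composition with an "Others" category, and culture/flow-cytometry/DNA
    bioburden bookkeeping with detection limits. A synthetic-community
    generator with planted ground truth makes every stage testable without
    sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    biomformat,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
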