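Package: lncmoa
Title: Mechanism-of-Action Triage for Nuclear Long Noncoding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated desk-scale pipeline for inferring how a nuclear long
    noncoding RNA (lncRNA) regulates its target genes. Quantifies RT-qPCR
    readouts (mean normalized expression, knockdown percent change with
    two-way ANOVA and Bonferroni post tests, subcellular fractionation
    percentages, RIP percent-of-input), selects consensus lncRNA-binding
    proteins from two predictor score tables, searches promoters for putative
    RNA:DNA triplex target sites under canonical Hoogsteen pairing rules,
    scans promoters with position weight matrices using exact null p-values,
    tests relative motif and transcription-factor-binding-site enrichment
    against background promoters, and prioritizes candidate partner
    transcription factors by evidence scoring, hierarchical clustering and
    intersection. Ships seeded synthetic-data generators with planted ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
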