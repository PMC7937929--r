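Package: fugupop
Title: Diagnostic-Marker Introgression and Selective-Sweep Scans for
    Multi-Species Resequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Population-genomic analyses for multi-species whole-genome
    resequencing cohorts of the pufferfish genus Takifugu and similar
    radiations: VCFTOOLS-style site filtering, per-site and windowed
    statistics (Weir-Cockerham and Hudson FST, nucleotide diversity,
    Tajima's D, LD decay), species-diagnostic fixed-difference marker
    discovery, per-individual introgression ratios with mitochondrial
    lineage assignment, windowed homozygote-ratio introgression mapping,
    a composite FST / pi-ratio selective-sweep scan with fine mapping,
    and a seeded multi-species genotype simulator with machine-readable
    truth for every downstream statistic.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
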