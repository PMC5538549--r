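Package: rohsplice
Title: Homozygosity Mapping and Intron-Retention Discovery for Recessive Splicing Defects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated discovery pipeline for recessive disease genes whose
    causal allele is a noncoding splicing mutation. Combines runs-of-homozygosity
    detection and a simplified recessive homozygosity LOD statistic on SNP
    genotypes, rare-noncoding-variant triage of VCF records against a gene model,
    splice-junction-based intron-retention quantification with exact tests and
    Holm control, allele-specific retention association, retained-intron open
    reading frame and nonsense-mediated-decay consequence prediction, and
    orthogonal RT-PCR fragment-area and delta-delta-Ct quantification. Seeded
    generators produce synthetic cohorts with the statistical structure the
    analysis assumes, so the whole pipeline is testable end to end without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
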