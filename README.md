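# rohsplice

An R package for discovering recessive-disease genes whose causal allele is
a **noncoding splicing mutation** — the case where DNA sequencing alone
dead-ends. It integrates the genomic and transcriptomic halves of that
analysis into one tested pipeline, aimed at statistical geneticists and
computational biologists working on Mendelian gene discovery:

1. **Homozygosity mapping** — per-individual runs of homozygosity from SNP
   genotypes, the minimal overlapping ROH across affecteds (with haplotype
   consistency flags), and a simplified recessive homozygosity LOD score
   `LOD = Σᵢ log₁₀ [P(gᵢ | autozygous) / P(gᵢ | random mating)]`.
2. **Variant triage** — Table-style classification of VCF records against
   gene models (nonsynonymous / synonymous / canonical splice (±2 bp) /
   UTR / intronic / intergenic) and the inclusive "≥1% in any database"
   rare-variant filter, summarized inside a candidate interval.
3. **Intron retention** — the junction-read statistic
   `R = spanning / (spanning + spliced)` per intron, pooled per genotype
   group with Wilson 95% CIs, all-pairs Fisher exact tests under Holm
   step-down control, and an exact binomial test of allele-specific
   retention at the variant position (*cis* evidence).
4. **Consequence** — the ORF of the retained-intron transcript: truncated
   protein length, aberrant residue count, premature-stop offset, and NMD
   prediction by the strict 50-nt last-junction rule.
5. **RT-PCR / qPCR** — percent-unspliced area ratios with group t-tests
   (Holm-controlled) and 2^(−ΔΔCt) relative expression with asymmetric
   t-based CIs.

Seeded generators (`gen_genotypes`, `gen_variant_fixture`,
`gen_junction_reads`, `gen_splice_quant`) produce synthetic cohorts with
the statistical structure the pipeline assumes, so everything above is
exercised end to end with no external data. `make_demo()` writes a complete
desk-scale cohort; `run_pipeline()` runs the whole discovery analysis from
a single JSON config.

## Worked example

```r
library(rohsplice)

dir <- tempfile()
cfg <- make_demo(dir, seed = 5)       # writes genotypes, VCF, reads, areas, Ct
report <- run_pipeline(cfg)

report$mapping$candidate_kb
#> [1] 733
report$triage$n_rare_noncoding
#> [1] 38
report$retention$focal_intron
#> [1] 6
subset(report$retention$per_group, intron == 6)
#>    intron    group spanning spliced proportion     ci_low   ci_high
#> 16      6 affected      892     428 0.67575758 0.65002733 0.7004678
#> 17      6  control       96    1464 0.06153846 0.05065632 0.0745747
#> 18      6   parent       84     636 0.11666667 0.09522639 0.1421757
report$retention$allelic$fraction
#> [1] 0.6976744
report$consequence$orf[c("mutant_protein_len", "wildtype_protein_len",
                         "aberrant_residues", "nmd_predicted")]
#> $mutant_protein_len   [1] 366
#> $wildtype_protein_len [1] 566
#> $aberrant_residues    [1] 17
#> $nmd_predicted        [1] TRUE
```

Reading the numbers: the affecteds' shared homozygous interval spans
733 kb and contains 38 rare noncoding variants (and no rare coding or
canonical-splice ones); intron 6 of the candidate gene is the top retention
hit, retained in ~68% of junction-informative reads in affected samples
versus ~6% in controls; among heterozygote reads covering the intronic
variant, ~70% carry the mutant base (retention is in *cis* with the
allele); and the retained intron truncates the 566-residue protein to 366
residues with 17 aberrant ones, with NMD predicted. Exact pooled counts
vary with the demo seed.

## Layout

- `R/` — implementation (coordinates/gene models, generators, ROH + LOD,
  triage, retention, consequence, RT-PCR/qPCR, pipeline)
- `tests/testthat/` — unit, property and acceptance tests with independent
  brute-force oracles (hypergeometric/binomial enumeration, codon-table
  translation, O(n²) run enumeration, exact permutation t)
- `vignettes/noncoding-discovery.Rmd` — the methods vignette: models,
  assumptions, parameter choices, what the synthetic data does and does
  not emulate
- `scripts/acceptance.R` — headline-quantity recomputation (above)
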