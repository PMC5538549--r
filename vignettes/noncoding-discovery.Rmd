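---
title: "Discovering noncoding splicing mutations by integrated homozygosity mapping and intron-retention analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering noncoding splicing mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohsplice)
```

## The problem this package addresses

Most Mendelian-disease pipelines stop at the exome: coding changes and the
two canonical splice-site bases are straightforward to interpret, everything
else is hard. When a recessive disease maps cleanly to a locus but the locus
contains *no* plausible coding or canonical-splice candidate, the causal
allele is probably noncoding, and DNA sequence alone cannot tell which of
the dozens of rare noncoding variants in the interval matters.
Transcriptome evidence can: a noncoding allele that damages splicing leaves
a footprint in RNA-seq — here, retention of the intron that carries it —
and the retained transcripts can be tied back to the allele itself through
the reads that cover the variant position.

`rohsplice` implements that integrated analysis as a reusable, tested
pipeline, together with seeded generators that produce synthetic cohorts
with exactly the statistical structure the analysis assumes. Every stage is
therefore testable end to end with no external data.

## The pipeline stages and their models

### Homozygosity mapping

Runs of homozygosity (ROH) are detected per individual as maximal runs of
homozygous SNP calls. A heterozygous call breaks a run; up to
`max_missing_run` consecutive missing calls are skipped but never bound a
segment nor count toward its marker support. Note that the *allele* being
homozygous may change from marker to marker within one run — within an
autozygous segment the individual is homozygous for one founder haplotype,
and that haplotype carries different alleles at different markers. Defaults
(`min_markers = 25`, `min_length_kb = 500`) follow common array-ROH
practice; they are deliberately conservative and both are configurable.

`het_tolerance` (default 0) lets a run absorb a bounded number of
heterozygous calls, implemented as a greedy absorb during the scan. The
default treats het calls as hard breakers; the demo pipeline configuration
raises the tolerance to 5 because its genotype simulation includes a
realistic per-call genotyping error rate (0.005) that converts occasional
truly-homozygous calls into het calls, and an analysis of such data should
not let isolated miscalls shatter a megabase-scale autozygous segment.

The candidate interval is the intersection, across affected individuals, of
each individual's ROH overlapping an anchor (for example the linkage peak
region). Markers at which two affecteds are homozygous for *different*
alleles are flagged as haplotype-inconsistent.

The accompanying LOD statistic is deliberately a simplified *singlepoint*
homozygosity-mapping score in the Lander–Botstein tradition, not a
multipoint pedigree likelihood: per marker,

$$\mathrm{LOD} = \sum_i \log_{10}
  \frac{P(g_i \mid \text{autozygous})}{P(g_i \mid \text{random mating})},$$

with $P(\text{hom}_a \mid \text{autozygous}) = (1-\varepsilon)\,q_a$,
$P(\text{het} \mid \text{autozygous}) = \varepsilon$,
$P(\text{hom}_a \mid \text{random}) = q_a^2$ and
$P(\text{het} \mid \text{random}) = 2 q_a q_b$. Recombination is not
modelled, pedigree structure is not used, and the statistic is additive
over individuals; it is meant to rank markers and localize the shared
segment, not to reproduce a Merlin multipoint score.

### Variant triage

Variants are classified against gene models with precedence
coding > canonical splice > UTR > intronic > intergenic; coding calls are
split synonymous/nonsynonymous by codon translation, canonical-splice means
within 2 bp of the intron–exon junction on the intronic side, and with
several transcripts the most severe call wins. The rarity filter is the
inclusive "at or above 1% in *any* population database" rule, with absent
frequencies treated as zero (a variant never seen in any database is rare).
The "rare noncoding" rollup that drives candidate counting is
intronic + intergenic; UTR variants are tabulated separately. Conservation
scores are intentionally not used for ranking: a causal noncoding allele
need not be conserved, and the analysis is designed to let functional
(transcriptome) evidence arbitrate instead.

Insertions/deletions are classified by their leftmost affected base — a
documented simplification; the synthetic fixtures only exercise SNVs.

### Intron retention from junction reads

The core statistic. For an intron $i$, a read is **spanning** if a
contiguous aligned block covers the donor or acceptor boundary with at
least `min_anchor` aligned bases on both sides (evidence the intron is
present in the mRNA), and **spliced** if its alignment gap coincides
exactly with the intron with `min_anchor` anchors on the flanking exons
(evidence it was removed). Everything else — including reads lying wholly
inside the intron — is uninformative. The retention estimate is

$$R = \frac{\text{spanning}}{\text{spanning} + \text{spliced}},$$

computed per sample and pooled per genotype group (pool-then-test, which is
how sparse junction evidence is usually aggregated); a read spanning both
boundaries of one intron counts once. The 95% interval is a Wilson score
interval by default (Clopper–Pearson via an argument); the Wilson interval
behaves well at the small pooled counts this estimator often sees near 0.
`min_anchor` defaults to 6 bp, a standard junction-confidence anchor.

Group differences use two-sided Fisher exact tests on the 2×2
spanning/spliced tables for all group pairs, with Holm step-down control
over the pairwise family. Allelic association in heterozygotes counts reads
by the base carried at the (intronic) variant position — only
intron-retaining reads can cover it — and tests the mutant-base fraction
against 0.5 with a two-sided exact binomial test. A mutant fraction above
one half ties the retention to the variant allele in *cis*. FPKM is
provided for simple expression summaries.

### Consequence prediction

Retaining an intron inside the CDS changes the reading frame downstream of
the donor unless the intron length is a multiple of three. The consequence
module translates the mutant coding sequence (wild-type CDS with the intron
inserted; translation runs on into the 3' UTR if no stop appears) and
reports the first in-frame stop. Two counting conventions are fixed and
documented because alternatives exist:

* `stop_offset_bp` is the number of intron bases *translated into protein*
  before termination; the stop codon itself begins at intron base
  `stop_offset_bp + 1`.
* `aberrant_residues` counts residues whose codon's **first** base is
  intronic, so the chimeric codon straddling the exon–intron junction is
  not counted aberrant.

On the packaged disease-gene fixture (junction after CDS base 1046, stop
after 52 bp of the 109-bp intron) these give a 366-residue truncated
protein — versus 566 wild-type — ending in 17 aberrant residues.

NMD prediction uses the classic exon-junction-complex rule: decay is
predicted iff the premature stop lies strictly more than `rule_nt = 50`
nucleotides upstream of the *final* exon–exon junction of the **mutant**
transcript (retaining intron $i$ removes junction $i$ from the set). A stop
in a retained final intron is therefore never predicted to trigger decay,
and a stop exactly 50 nt upstream is not either.

### RT-PCR and qPCR quantification

The orthogonal wet-lab quantifications are modelled exactly as performed:
percent unspliced product is
$100\,A_u/(A_u + A_s)$ over fluorescence areas — a *relative* measure,
since the two products amplify with different efficiencies — summarized
per group with pairwise two-tailed unpaired t-tests and Holm control.
Pooled-variance Student's t is the default with Welch available via
`var_equal = FALSE`; the choice is documented rather than consequential,
and the permutation-test cross-check in the test suite holds for either.
Relative expression is $2^{-\Delta\Delta C_t}$ with a two-sample
t-interval on $\Delta\Delta C_t$ exponentiated into an asymmetric CI.

## What the synthetic generators emulate

The generators are first-class, tested code; their defaults *are* the study
conditions the pipeline is designed for.

* `gen_genotypes()`: a consanguineous cohort (7 affected, 15 parents by
  default) on a 2000-marker map, with a shared autozygous core segment at
  the disease ROH, per-affected random extension of that segment (up to
  300 kb per side), Hardy–Weinberg draws elsewhere, per-call missingness
  (0.01) and genotyping error (0.005) that renders autozygous calls
  heterozygous. Parents carry one founder haplotype over the core.
* `gen_variant_fixture()`: by construction, 18 rare intronic (always
  including the focal splice-region variant) and 20 rare intergenic
  variants inside the ROH — 38 rare noncoding — zero rare coding or
  canonical-splice variants inside it, 25 common variants inside, and 5
  rare coding variants in a bystander gene outside, each record carrying
  four per-database allele frequencies.
* `gen_junction_reads()`: per-allele retention of the focal intron at 0.66
  (homozygous mutant), 0.07 (wild type), and a heterozygote whose wild-type
  allele retains at the control rate while the mutant-allele rate is solved
  from the pooled heterozygote value 0.12 — under equal allelic output,
  $r_{mut} = 2 \times 0.12 - 0.07 = 0.17$, which makes the expected
  mutant-base fraction among variant-covering reads
  $0.17/(0.17+0.07) \approx 71\%$. Non-focal introns retain at a 0.02
  baseline. Every simulated read is junction-informative by construction,
  so the estimator is exercised exactly at its definition; read depth per
  intron is a free parameter (the study does not constrain it).
* `gen_splice_quant()`: true fraction-unspliced drawn per sample from
  truncated normal group distributions (0.85/0.05, 0.38/0.13, 0.24/0.10),
  split over a log-normal total area so the per-sample ratio equals the
  drawn fraction; Ct pairs drawn so expected relative expression matches
  the configured values (heterozygous parents 0.56; the affected-group
  0.35 is a free parameter, chosen as a plausible value for a genotype
  with two decay-targeted alleles, since the corresponding cell lines
  cannot be grown and measured).

What they deliberately do **not** model: sequencing error, base qualities,
fragment-length distributions, alignment ambiguity, novel isoforms, CNVs,
pedigree recombination structure. Passing tests therefore demonstrate the
*statistical machinery* is correct at the study's parameter regime — they
do not demonstrate robustness to alignment artifacts or to error modes the
generators omit.

## Numerical and design choices

* Coordinates are 1-based inclusive (VCF-style) internally; BED12 is
  converted at the file boundary. Interval sizes in kb use
  `round((end - start)/1000)` with half-up rounding; at kb precision the
  ±1 bp inclusive-length question is immaterial.
* Intron numbering follows transcript order, so intron $k$ of a
  minus-strand gene sits at higher genomic coordinates than exon $k+1$;
  HGVS-style `c.X-k` positions resolve by walking $k$ bases into the
  intron from the acceptor-adjacent exon base, respecting strand.
* Zero informative reads yield a missing retention estimate, never 0.
* Ties in the intronic distance-to-junction (equidistant donor/acceptor)
  resolve to the donor side; nothing downstream depends on the tie-break.
* All generators draw from one seeded RNG per call and restore the
  caller's RNG state; seeds are required arguments.
* Problem sizes used by the test-suite recovery checks: ≥10^4
  junction-informative reads per pooled group for retention recovery
  (tolerance ±2 percentage points), ≥5×10^3 variant-covering reads for the
  allelic fraction (±3 points), and 20 samples per group for the
  fragment-area recovery (±3 points). These sizes make the stochastic
  tolerances comfortable without being wasteful.

## Limitations

The LOD score is singlepoint and ignores pedigree structure, so its
absolute magnitude is not comparable to a multipoint pedigree likelihood on
the same data. Read classification consumes the simplified junction-read
table (or any alignment reducible to match/gap blocks); it does not parse
BAM qualities or mapping flags. Consequence prediction considers the
annotated start codon only (no reinitiation) and reports the most severe
call across supplied transcripts rather than arbitrating isoform usage.
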