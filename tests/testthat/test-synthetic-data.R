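test_that("all generators are deterministic under a fixed seed", {
  s1 <- gen_genotypes(cohort_spec(seed = 9, marker_count = 400))
  s2 <- gen_genotypes(cohort_spec(seed = 9, marker_count = 400))
  expect_identical(s1, s2)
  s3 <- gen_genotypes(cohort_spec(seed = 10, marker_count = 400))
  expect_false(identical(s1$genotypes, s3$genotypes))

  cfg <- read_sim_config(depth = 20, seed = 4)
  expect_identical(gen_junction_reads(cfg), gen_junction_reads(cfg))

  q1 <- gen_splice_quant(splice_quant_config(seed = 8))
  expect_identical(q1, gen_splice_quant(splice_quant_config(seed = 8)))

  f1 <- gen_variant_fixture(seed = 7)
  expect_identical(f1$variants, gen_variant_fixture(seed = 7)$variants)
})

test_that("error-free affecteds are homozygous across their truth segment", {
  co <- gen_genotypes(cohort_spec(seed = 21, marker_count = 600,
                                  error_rate = 0, missing_rate = 0))
  for (i in seq_len(nrow(co$truth))) {
    id <- co$truth$individual[i]
    inside <- co$markers$pos >= co$truth$start[i] &
      co$markers$pos <= co$truth$end[i]
    calls <- co$genotypes[id, inside]
    expect_true(all(calls %in% c("AA", "BB")))
    ## homozygous for the founder haplotype, not an arbitrary allele
    expect_identical(unname(substr(calls, 1, 1)), co$founder[inside])
  }
})

test_that("heterozygous miscalls inside segments match the error rate", {
  eps <- 0.02
  co <- gen_genotypes(cohort_spec(seed = 33, marker_count = 1000,
                                  n_affected = 7, error_rate = eps,
                                  missing_rate = 0))
  n_het <- 0; n_tot <- 0
  for (i in seq_len(nrow(co$truth))) {
    inside <- co$markers$pos >= co$truth$start[i] &
      co$markers$pos <= co$truth$end[i]
    calls <- co$genotypes[co$truth$individual[i], inside]
    n_het <- n_het + sum(calls == "AB")
    n_tot <- n_tot + length(calls)
  }
  ## binomial tolerance: 4 standard deviations around eps * n
  expect_lt(abs(n_het - eps * n_tot), 4 * sqrt(eps * (1 - eps) * n_tot) + 1)
})

test_that("degenerate retention probabilities produce pure read classes", {
  base <- list(gene = synthetic_gene_model(), introns = 6, depth = 300)
  one_sample <- data.frame(sample_id = "s1", group = "g", genotype = "hom_mut")
  cfg1 <- read_sim_config(gene = base$gene, samples = one_sample,
                          retention = c(hom_ref = 0.07, het_pooled = 0.12,
                                        hom_mut = 1),
                          introns = 6, depth = 300, seed = 2)
  r1 <- gen_junction_reads(cfg1)$reads
  cls1 <- classify_reads(r1, base$gene$model, 6)
  expect_true(all(cls1 == "spanning"))
  cfg0 <- read_sim_config(gene = base$gene, samples = one_sample,
                          retention = c(hom_ref = 0.07, het_pooled = 0.12,
                                        hom_mut = 0),
                          introns = 6, depth = 300, seed = 2)
  r0 <- gen_junction_reads(cfg0)$reads
  expect_true(all(classify_reads(r0, base$gene$model, 6) == "spliced"))
})

test_that("no read from the wild-type background carries the mutant base", {
  cfg <- read_sim_config(depth = 80, introns = 6, seed = 14)
  sim <- gen_junction_reads(cfg)
  v <- cfg$gene$variant
  carriers <- sim$reads[!is.na(sim$reads$base_at_variant) &
                          sim$reads$base_at_variant == v$alt, ]
  expect_true(all(carriers$genotype %in% c("het", "hom_mut")))
  hom_ref <- sim$reads[sim$reads$genotype == "hom_ref", ]
  expect_false(any(hom_ref$base_at_variant == v$alt, na.rm = TRUE))
  ## solved heterozygote allele rates reproduce the pooled value
  expect_equal(mean(cfg$allele_rates$het), cfg$retention[["het_pooled"]])
})

test_that("variant fixture constructs the documented truth labels", {
  fx <- gen_variant_fixture(seed = 7)
  expect_equal(sum(fx$truth$class == "intronic" & fx$truth$rarity == "rare" &
                     fx$truth$in_roh), 18)
  expect_equal(sum(fx$truth$class == "intergenic" & fx$truth$rarity == "rare" &
                     fx$truth$in_roh), 20)
  expect_equal(sum(fx$truth$class == "coding" & fx$truth$in_roh), 0)
  ## the focal variant is one of the rare intronic records
  expect_true(fx$gene$variant$pos %in%
                fx$truth$pos[fx$truth$class == "intronic"])
  ## every common-labelled record is at/above 1% in at least one database
  ## (rows absent from every database count as frequency 0)
  afc <- grep("^AF_", names(fx$variants))
  af <- as.matrix(fx$variants[, afc])
  af[is.na(af)] <- 0
  max_af <- apply(af, 1, max)
  expect_true(all(max_af[fx$truth$rarity == "common"] >= 0.01))
  expect_true(all(max_af[fx$truth$rarity == "rare"] < 0.01))
})

test_that("a zero-variant fixture writes a valid empty-bodied VCF", {
  fx <- gen_variant_fixture(seed = 3, n_rare_intronic = 0,
                            n_rare_intergenic = 0, n_common = 0,
                            n_rare_coding_outside = 0)
  path <- tempfile(fileext = ".vcf")
  write_variants_vcf(fx, path)
  lines <- readLines(path)
  expect_true(all(grepl("^#", lines)))
  v <- read_variants_vcf(path)
  expect_equal(nrow(v), 0)
})

test_that("VCF writing and parsing round-trip the allele frequencies", {
  fx <- gen_variant_fixture(seed = 11)
  path <- tempfile(fileext = ".vcf")
  write_variants_vcf(fx, path)
  v <- read_variants_vcf(path)
  expect_equal(nrow(v), nrow(fx$variants))
  expect_equal(v$pos, fx$variants$pos)
  expect_equal(v$ref, fx$variants$ref)
  orig <- as.matrix(fx$variants[, grep("^AF_", names(fx$variants))])
  parsed <- as.matrix(v[, grep("^AF_", names(v))])
  expect_equal(unname(parsed), unname(orig), tolerance = 1e-5)
})

test_that("noise-free splice quantification hits the group means exactly", {
  cfg <- splice_quant_config(
    groups = data.frame(group = c("a", "b"), n = 5,
                        mean_frac = c(0.85, 0.24), sd_frac = 0,
                        rel_expr = c(0.5, 1)),
    dct_sd = 0, reference_group = "b", seed = 5)
  q <- gen_splice_quant(cfg)
  pct <- percent_unspliced(q$areas$area_unspliced, q$areas$area_spliced)
  expect_equal(unname(pct[q$areas$group == "a"]), rep(85, 5))
  expect_equal(unname(pct[q$areas$group == "b"]), rep(24, 5))
  ## relative expression 0.5 recovered exactly through the ddCt pathway
  rel <- ddct_relative(q$ct, reference_group = "b")
  expect_equal(rel$relative[rel$group == "a"], 0.5)
  expect_equal(rel$relative[rel$group == "b"], 1)
})

test_that("splice quantification recovers configured group means", {
  q <- gen_splice_quant(splice_quant_config(seed = 3))
  gs <- group_summary(q$areas)
  s <- gs$summary
  expect_lt(abs(s$mean[s$group == "affected"] - 85), 3)
  expect_lt(abs(s$mean[s$group == "parent"] - 38), 3)
  expect_lt(abs(s$mean[s$group == "control"] - 24), 3)
})
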