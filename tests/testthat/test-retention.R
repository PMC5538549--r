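test_that("read classification follows the junction-evidence definition", {
  fix <- synthetic_gene_model()
  m <- fix$model
  i6 <- m$introns[m$introns$intron == 6, ]       # [33582056, 33582164]
  s <- i6$start; e <- i6$end
  reads <- data.frame(
    chrom = "chr21",
    pos = c(s - 47,      # gapped read, 47M 109N 53M: exact splice
            s - 40,      # contiguous 100M over the acceptor boundary: 40 + 60
            e - 96,      # contiguous 100M ending 3 bp past the donor boundary
            s + 2),      # wholly intronic read
    cigar = c("47M109N53M", "100M", "100M", "50M"))
  cls <- classify_reads(reads, m, 6, min_anchor = 6)
  expect_equal(cls, c("spliced", "spanning", "uninformative",
                      "uninformative"))
  ## the same gapped read is uninformative for every other intron
  expect_equal(classify_reads(reads[1, ], m, 5), "uninformative")
  ## gap must match the intron exactly
  off_by_one <- data.frame(chrom = "chr21", pos = s - 47,
                           cigar = "47M108N53M")
  expect_equal(classify_reads(off_by_one, m, 6), "uninformative")
  expect_error(cigar_blocks(1, "10M5X10M"), "malformed")
})

test_that("a read spanning both boundaries of an intron counts once", {
  toy <- make_toy_gene(12, n_exons = 3, strand = "+",
                       exon_lens = c(60, 60, 60), intron_lens = c(20, 40))
  m <- toy$model
  i1 <- m$introns[1, ]
  ## 60M read covering the whole 20-bp intron 1 plus 20 bp of each exon
  reads <- data.frame(sample_id = "s1", group = "g", chrom = "chrT",
                      pos = i1$start - 20, cigar = "60M")
  expect_equal(classify_reads(reads, m, 1), "spanning")
  counts <- count_junctions(reads, m)
  pg <- counts$per_group
  expect_equal(pg$spanning[pg$intron == 1], 1)
  expect_equal(sum(pg$spanning), 1)
  ## empty read set gives an all-zero table
  counts0 <- count_junctions(reads[0, ], m, groups = c(s1 = "g"))
  expect_true(all(counts0$per_group$spanning == 0))
  expect_true(all(counts0$per_group$spliced == 0))
})

test_that("pooled counts sum member samples and mirror the 66/34 example", {
  est <- retention_estimate(66, 34)
  expect_equal(est$proportion, 0.66)
  toy <- make_toy_gene(12, n_exons = 3, strand = "+",
                       exon_lens = c(60, 60, 60), intron_lens = c(20, 40))
  i1 <- toy$model$introns[1, ]
  mk <- function(sample, n_span, n_spl) {
    rbind(
      if (n_span) data.frame(sample_id = sample, group = "aff",
                             chrom = "chrT", pos = rep(i1$start - 10, n_span),
                             cigar = "30M"),
      if (n_spl) data.frame(sample_id = sample, group = "aff",
                            chrom = "chrT", pos = rep(i1$start - 10, n_spl),
                            cigar = "10M20N20M"))
  }
  reads <- rbind(mk("s1", 40, 20), mk("s2", 26, 14))
  pg <- count_junctions(reads, toy$model)$per_group
  expect_equal(pg$spanning[pg$intron == 1], 66)
  expect_equal(pg$spliced[pg$intron == 1], 34)
  per_s <- count_junctions(reads, toy$model)$per_sample
  expect_equal(sum(per_s$spanning[per_s$intron == 1]),
               pg$spanning[pg$intron == 1])
})

test_that("Wilson intervals match hand evaluation and order correctly", {
  est <- retention_estimate(7, 93)
  expect_equal(est$proportion, 0.07)
  ## hand evaluation of the Wilson formula at z = 1.96: (0.0343, 0.1375)
  expect_equal(est$ci_low, 0.03431926, tolerance = 1e-4)
  expect_equal(est$ci_high, 0.13749515, tolerance = 1e-4)
  z <- retention_estimate(0, 50)
  expect_equal(z$proportion, 0)
  expect_equal(z$ci_low, 0)
  na <- retention_estimate(0, 0)
  expect_true(is.na(na$proportion) && is.na(na$ci_low))
  set.seed(3)
  for (i in 1:50) {
    a <- sample(0:80, 1); b <- sample(0:80, 1)
    if (a + b == 0) next
    for (method in c("wilson", "clopper-pearson")) {
      e <- retention_estimate(a, b, method = method)
      expect_true(e$ci_low >= 0 && e$ci_low <= e$proportion)
      expect_true(e$ci_high <= 1 && e$ci_high >= e$proportion)
    }
  }
})

test_that("pairwise Fisher tests match brute-force enumeration", {
  flat <- compare_groups(data.frame(group = c("a", "b"),
                                    spanning = c(5, 5), spliced = c(5, 5)))
  expect_equal(flat$p, 1)
  sharp <- compare_groups(data.frame(group = c("a", "b"),
                                     spanning = c(8, 1), spliced = c(2, 9)))
  expect_equal(sharp$p, 0.005477, tolerance = 1e-4)
  expect_equal(sharp$p, oracle_fisher(matrix(c(8, 1, 2, 9), 2)),
               tolerance = 1e-9)
  set.seed(17)
  for (i in 1:60) {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- compare_groups(data.frame(group = c("a", "b"),
                                     spanning = tab[, 1],
                                     spliced = tab[, 2]))$p
    expect_equal(got, oracle_fisher(t(tab)), tolerance = 1e-8)
  }
  expect_error(compare_groups(data.frame(group = c("a", "b"),
                                         spanning = c(0, 5),
                                         spliced = c(0, 5))),
               "zero informative")
})

test_that("Holm adjustment follows the step-down definition", {
  ## three-group comparison: adjusted values match the oracle on raw p
  counts <- data.frame(group = c("g1", "g2", "g3"),
                       spanning = c(30, 18, 5), spliced = c(20, 32, 45))
  cmp <- compare_groups(counts)
  expect_equal(cmp$p_holm, oracle_holm(cmp$p))
  expect_true(all(cmp$p_holm >= cmp$p))
  expect_true(all(cmp$p_holm <= 1))
  ## the worked step-down example
  expect_equal(oracle_holm(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_equal(stats::p.adjust(c(0.01, 0.03, 0.04), "holm"),
               c(0.03, 0.06, 0.06))
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(1:6, 1))
    expect_equal(stats::p.adjust(p, "holm"), oracle_holm(p))
  }
})

test_that("the allelic binomial test matches exact pmf enumeration", {
  a <- allelic_association(c(rep("C", 7), rep("T", 3)), ref = "T", alt = "C")
  expect_equal(a$fraction, 0.7)
  expect_equal(a$p, 0.34375)
  expect_equal(a$p, oracle_binom(7, 10))
  even <- allelic_association(c(rep("C", 5), rep("T", 5)), "T", "C")
  expect_equal(even$fraction, 0.5)
  expect_equal(even$p, 1)
  expect_error(allelic_association(character(0), "T", "C"), "no reads")
  expect_error(allelic_association(c(NA_character_, NA), "T", "C"),
               "no reads")
  ## other bases are excluded but reported
  g <- allelic_association(c("C", "C", "T", "G"), "T", "C")
  expect_equal(g$n_other, 1)
  expect_equal(g$fraction, 2 / 3)
  for (n in c(25, 400, 10000)) {
    k <- rbinom(1, n, 0.55)
    got <- stats::binom.test(k, n, 0.5)$p.value
    expect_equal(got, oracle_binom(k, n), tolerance = 1e-9)
  }
})

test_that("FPKM follows its normalization formula", {
  expect_equal(fpkm(1000, 2000, 1e7), 50)
  expect_equal(fpkm(0, 2000, 1e7), 0)
  expect_equal(fpkm(1000, 2000, 2e7), 25)    # doubling depth halves FPKM
  expect_error(fpkm(10, 0, 1e6), "length")
  expect_error(fpkm(10, 100, 0), "total")
})

test_that("the estimator recovers simulated retention rates", {
  cfg <- read_sim_config(
    samples = data.frame(sample_id = sprintf("a%02d", 1:5),
                         group = "affected", genotype = "hom_mut"),
    depth = 2200, introns = 6, seed = 11)
  sim <- gen_junction_reads(cfg)
  pg <- count_junctions(sim$reads, cfg$gene$model)$per_group
  pg <- pg[pg$intron == 6, ]
  est <- retention_estimate(pg$spanning, pg$spliced)
  expect_gte(pg$spanning + pg$spliced, 1e4)
  expect_lt(abs(est$proportion - sim$truth$pooled_retention[["hom_mut"]]),
            0.02)
})

test_that("heterozygote reads show the cis allelic retention signal", {
  cfg <- read_sim_config(
    samples = data.frame(sample_id = sprintf("h%02d", 1:6),
                         group = "parent", genotype = "het"),
    depth = 3000, introns = 6, seed = 19)
  sim <- gen_junction_reads(cfg)
  aa <- allelic_association(sim$reads$base_at_variant,
                            cfg$gene$variant$ref, cfg$gene$variant$alt)
  expect_gt(aa$fraction, 0.5)
  expect_lt(aa$p, 0.05)
  expect_lt(abs(aa$fraction - sim$truth$expected_mutant_fraction), 0.05)
})

test_that("per-intron group pattern shows the focal defect only", {
  cfg <- read_sim_config(depth = 150, seed = 23)
  sim <- gen_junction_reads(cfg)
  pg <- count_junctions(sim$reads, cfg$gene$model)$per_group
  pg$prop <- pg$spanning / (pg$spanning + pg$spliced)
  focal <- pg[pg$intron == 6, ]
  expect_gt(focal$prop[focal$group == "affected"],
            focal$prop[focal$group == "parent"])
  expect_gt(focal$prop[focal$group == "parent"],
            focal$prop[focal$group == "control"])
  other <- pg[pg$intron != 6, ]
  expect_true(all(other$prop < 0.06))     # near the 0.02 baseline
  ## pooled group comparisons are extreme for affected contrasts
  cmp <- compare_groups(focal[, c("group", "spanning", "spliced")])
  aff <- cmp$group1 == "affected" | cmp$group2 == "affected"
  expect_true(all(cmp$p_holm[aff] < 1e-10))
})
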