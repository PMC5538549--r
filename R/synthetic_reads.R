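#' Configuration for the junction-read simulator
#'
#' Describes an RNA-seq read simulation over a toy multi-exon gene with one
#' poorly spliced focal intron whose retention probability depends on
#' genotype and allele. Default retention values encode the study
#' conditions: 0.66 per allele in homozygous mutants, 0.07 in wild-type
#' controls, and a pooled heterozygote value of 0.12 with the wild-type
#' allele held at the control rate — so the mutant-allele rate is solved as
#' `2 * 0.12 - 0.07 = 0.17` under equal allelic transcript output. Non-focal
#' introns retain at a low genotype-independent baseline.
#'
#' @param gene a `gene_fixture` from [synthetic_gene_model()].
#' @param samples data.frame with `sample_id`, `group`, `genotype`
#'   (`hom_ref`/`het`/`hom_mut`); default 13 controls, 6 parents, 11
#'   affecteds, matching a 30-sample RNA-seq cohort.
#' @param retention named numeric: `hom_ref`, `het_pooled`, `hom_mut` focal
#'   intron retention (per-allele for the homozygous genotypes; pooled for
#'   heterozygotes).
#' @param baseline retention probability of non-focal introns.
#' @param focal_intron intron number with the splicing defect.
#' @param read_length simulated read length in bp.
#' @param min_anchor minimum aligned bases flanking a junction in simulated
#'   reads (matches the classifier default).
#' @param depth junction-informative reads simulated per intron per sample.
#' @param introns which introns to simulate (default all).
#' @param seed integer seed (required).
#' @return an object of class `read_sim_config`, with the solved per-allele
#'   heterozygote rates in `$allele_rates`.
#' @export
read_sim_config <- function(gene = synthetic_gene_model(),
                            samples = NULL,
                            retention = c(hom_ref = 0.07, het_pooled = 0.12,
                                          hom_mut = 0.66),
                            baseline = 0.02, focal_intron = NULL,
                            read_length = 100, min_anchor = 6, depth = 200,
                            introns = NULL, seed) {
  if (is.null(samples))
    samples <- data.frame(
      sample_id = c(sprintf("ctl%02d", 1:13), sprintf("par%02d", 1:6),
                    sprintf("aff%02d", 1:11)),
      group = rep(c("control", "parent", "affected"), c(13, 6, 11)),
      genotype = rep(c("hom_ref", "het", "hom_mut"), c(13, 6, 11)))
  stopifnot(all(c("sample_id", "group", "genotype") %in% names(samples)),
            all(samples$genotype %in% c("hom_ref", "het", "hom_mut")),
            all(c("hom_ref", "het_pooled", "hom_mut") %in% names(retention)))
  if (any(retention < 0 | retention > 1) || baseline < 0 || baseline > 1)
    stop("retention probabilities must lie in [0, 1]")
  focal_intron <- focal_intron %||% gene$variant$intron
  introns <- introns %||% gene$model$introns$intron
  het_mut <- 2 * retention[["het_pooled"]] - retention[["hom_ref"]]
  if (het_mut < 0 || het_mut > 1)
    stop("heterozygote pooled retention inconsistent with the control rate")
  if (read_length < 2 * min_anchor)
    stop("read length must be at least twice the minimum anchor")
  allele_rates <- list(
    hom_ref = c(ref = retention[["hom_ref"]], mut = retention[["hom_ref"]]),
    het = c(ref = retention[["hom_ref"]], mut = het_mut),
    hom_mut = c(ref = retention[["hom_mut"]], mut = retention[["hom_mut"]]))
  structure(list(gene = gene, samples = samples, retention = retention,
                 allele_rates = allele_rates, baseline = baseline,
                 focal_intron = focal_intron, read_length = read_length,
                 min_anchor = min_anchor, depth = depth, introns = introns,
                 seed = seed),
            class = "read_sim_config")
}

#' Simulate junction-informative RNA-seq reads with truth retention rates
#'
#' For every simulated fragment an allele is chosen from the sample's
#' genotype, retained-vs-spliced is drawn with that allele's retention
#' probability, and the read is placed so it is junction-informative:
#' retained fragments yield a contiguous read spanning the intron's donor or
#' acceptor boundary (chosen uniformly), spliced fragments yield a gapped
#' read whose gap exactly matches the intron, both with at least
#' `min_anchor` bases on each side. Reads covering the focal variant
#' position record the base they carry there: the mutant base appears only
#' on mutant-allele reads that retain the focal intron and reach the
#' position.
#'
#' @param cfg a [read_sim_config()].
#' @return list with `reads` (data.frame `read_id`, `sample_id`, `group`,
#'   `genotype`, `chrom`, `pos`, `cigar`, `base_at_variant`) and `truth`
#'   (per-genotype allele rates and expected pooled proportions).
#' @export
gen_junction_reads <- function(cfg) {
  stopifnot(inherits(cfg, "read_sim_config"))
  model <- cfg$gene$model
  v <- cfg$gene$variant
  rl <- cfg$read_length
  with_seed(cfg$seed, {
    parts <- list()
    for (si in seq_len(nrow(cfg$samples))) {
      geno <- cfg$samples$genotype[si]
      rates <- cfg$allele_rates[[geno]]
      for (i in cfg$introns) {
        irow <- model$introns[model$introns$intron == i, ]
        s <- irow$start; e <- irow$end; ilen <- e - s + 1
        n <- cfg$depth
        allele <- if (geno == "hom_ref") rep("ref", n)
                  else if (geno == "hom_mut") rep("mut", n)
                  else sample(c("ref", "mut"), n, replace = TRUE)
        r <- if (i == cfg$focal_intron) unname(rates[allele])
             else rep(cfg$baseline, n)
        retained <- runif(n) < r
        ## anchor offset: bases aligned on the left of the junction
        off <- sample(cfg$min_anchor:(rl - cfg$min_anchor), n, replace = TRUE)
        pos <- numeric(n); cigar <- character(n)
        base <- rep(NA_character_, n)
        at_acceptor <- runif(n) < 0.5   # which boundary a spanning read straddles
        ## genomic acceptor-adjacent boundary is (s-1 | s); donor is (e | e+1)
        ## (transcript-strand labels swap on '-', placement is symmetric)
        sp <- retained
        pos[sp & at_acceptor] <- s - off[sp & at_acceptor]
        pos[sp & !at_acceptor] <- e - off[sp & !at_acceptor] + 1
        cigar[sp] <- paste0(rl, "M")
        pos[!sp] <- s - off[!sp]
        cigar[!sp] <- sprintf("%dM%dN%dM", off[!sp], ilen, rl - off[!sp])
        if (i == v$intron) {
          covers <- sp & pos <= v$pos & pos + rl - 1 >= v$pos
          base[covers] <- ifelse(allele[covers] == "mut", v$alt, v$ref)
        }
        parts[[length(parts) + 1L]] <- data.frame(
          sample_id = cfg$samples$sample_id[si],
          group = cfg$samples$group[si], genotype = geno, intron = i,
          chrom = model$chrom, pos = pos, cigar = cigar,
          base_at_variant = base, stringsAsFactors = FALSE)
      }
    }
    reads <- do.call(rbind, parts)
    reads <- cbind(read_id = sprintf("r%07d", seq_len(nrow(reads))), reads)
    pooled <- vapply(cfg$allele_rates, mean, numeric(1))
    truth <- list(allele_rates = cfg$allele_rates,
                  pooled_retention = pooled,
                  baseline = cfg$baseline,
                  expected_mutant_fraction =
                    cfg$allele_rates$het[["mut"]] /
                    sum(cfg$allele_rates$het))
    list(reads = reads, truth = truth)
  })
}

#' Write / read the simplified junction-read TSV
#' @param reads data.frame as produced by [gen_junction_reads()].
#' @param path TSV path.
#' @return `path` (writer) or the reads data.frame (reader).
#' @export
write_reads_tsv <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "NA")
}
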