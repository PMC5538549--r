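#' Write a complete synthetic discovery cohort to disk
#'
#' Generates, at desk scale, every input the discovery pipeline consumes —
#' SNP genotypes, a variant VCF, gene models (GFF-lite) with genomic
#' sequence (FASTA), junction reads, RT-PCR areas and qPCR Ct values —
#' together with a `truth.json` sidecar holding the generators' latent truth
#' and a `config.json` that [run_pipeline()] can consume directly. All
#' randomness derives from `seed`; the same seed reproduces the bundle
#' byte for byte.
#'
#' @param outdir output directory (created if missing).
#' @param seed integer seed.
#' @param read_depth junction-informative reads per intron per sample.
#' @param n_quant samples per group in the splice-quantification tables.
#' @return invisible path of the written `config.json`.
#' @export
make_demo <- function(outdir, seed, read_depth = 120, n_quant = 20) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  seed <- as.integer(seed)

  gene <- synthetic_gene_model()
  bystander <- synthetic_bystander_gene()

  cohort <- gen_genotypes(cohort_spec(seed = seed + 1L))
  write_genotypes_tsv(cohort, file.path(outdir, "genotypes.tsv"),
                      file.path(outdir, "markers.tsv"))

  fixture <- gen_variant_fixture(seed = seed + 2L, gene = gene,
                                 bystander = bystander)
  write_variants_vcf(fixture, file.path(outdir, "variants.vcf"))

  rcfg <- read_sim_config(gene = gene, depth = read_depth, seed = seed + 3L)
  sim <- gen_junction_reads(rcfg)
  write_reads_tsv(sim$reads, file.path(outdir, "reads.tsv"))

  qcfg <- splice_quant_config(seed = seed + 4L)
  qcfg$groups$n <- n_quant
  quant <- gen_splice_quant(qcfg)
  write_quant_tsv(quant$areas, file.path(outdir, "areas.tsv"))
  write_quant_tsv(quant$ct, file.path(outdir, "ct.tsv"))

  write_gene_model_gff(list(gene$model, bystander$model),
                       file.path(outdir, "genes.gff"))
  write_genome_fasta(c(gene$genome, bystander$genome),
                     file.path(outdir, "genome.fa"))

  truth <- list(
    roh = fixture$roh[c("chrom", "start", "end")],
    cohort_segments = cohort$truth,
    variant_counts = as.list(table(paste(fixture$truth$class,
                                         fixture$truth$rarity))),
    retention = sim$truth,
    splice_quant = quant$truth)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## exon-6 / exon-7 primers for the amplicon computation (61 + 60 bp)
  config <- list(
    seed = seed,
    inputs = list(genotypes = "genotypes.tsv", markers = "markers.tsv",
                  variants = "variants.vcf", reads = "reads.tsv",
                  areas = "areas.tsv", ct = "ct.tsv",
                  gene_models = "genes.gff", genome = "genome.fa"),
    focal_transcript = gene$model$transcript_id,
    anchor = list(chrom = "chr21", start = 33344469, end = 34196070),
    variant = gene$variant[c("chrom", "pos", "ref", "alt")],
    params = list(af_threshold = 0.01, min_anchor = 6,
                  min_markers = 25, min_length_kb = 500, max_missing_run = 5,
                  het_tolerance = 5, lod_error_rate = 0.005, rule_nt = 50,
                  reference_group = "control"),
    primers = list(fwd = list(chrom = "chr21", start = 33582206,
                              end = 33582225),
                   rev = list(chrom = "chr21", start = 33581996,
                              end = 33582015)))
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(cfg_path)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

as_interval <- function(x, strand = "*") {
  genomic_interval(x$chrom, x$start, x$end, strand)
}

#' Run the integrated discovery pipeline from a config file
#'
#' Executes, in dependency order: ROH detection and minimal-overlap
#' candidate-interval mapping with a per-marker homozygosity LOD scan;
#' variant triage inside the candidate interval; per-intron retention
#' quantification with pairwise exact tests, Holm control and allelic
#' association at the configured variant; retained-intron consequence and
#' NMD prediction for the top retention hit; and RT-PCR / qPCR splice
#' quantification. A stage failure is reported with the stage's name. The
#' report contains no timestamps, so a given config + seed reproduces it
#' byte for byte.
#'
#' @param config path to a `config.json` written by [make_demo()] (or a
#'   pre-parsed list with an attribute-free equivalent structure; relative
#'   input paths are resolved against the config file's directory).
#' @param outdir optional directory; when given, `report.json` plus
#'   retention/triage/comparison TSVs are written there.
#' @return the discovery report (list), invisibly when `outdir` is given.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) {
    cfg_path <- config
    cfg <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
    base <- dirname(config)
    cfg_hash <- unname(tools::md5sum(cfg_path))
  } else {
    cfg <- config
    base <- "."
    tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
    cfg_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  pth <- function(key) {
    p <- cfg$inputs[[key]]
    if (is.null(p)) stop("config lacks input path '", key, "'")
    if (!file.exists(file.path(base, p)))
      stop("input file not found: ", file.path(base, p))
    file.path(base, p)
  }
  prm <- cfg$params

  ## --- homozygosity mapping -------------------------------------------
  mapping <- run_stage("roh", {
    geno <- read_genotypes_tsv(pth("genotypes"), pth("markers"))
    aff <- geno$samples$id[geno$samples$role == "affected"]
    calls_of <- function(id) data.frame(marker = geno$markers$id,
                                        pos = geno$markers$pos,
                                        call = geno$genotypes[id, ])
    segs <- lapply(aff, function(id)
      detect_roh(calls_of(id), individual = id,
                 chrom = geno$markers$chrom[1],
                 min_markers = prm$min_markers,
                 min_length_kb = prm$min_length_kb,
                 max_missing_run = prm$max_missing_run,
                 het_tolerance = prm$het_tolerance %||% 0))
    names(segs) <- aff
    anchor <- as_interval(cfg$anchor)
    overlap <- minimal_overlap_roh(segs, anchor)
    ## marker allele frequencies estimated from unaffected samples
    ## (Laplace-smoothed), never from generator truth
    unaff <- geno$samples$id[geno$samples$role != "affected"]
    gsub_ <- geno$genotypes[unaff, , drop = FALSE]
    n_a <- colSums(gsub_ == "AA") * 2 + colSums(gsub_ == "AB")
    n_tot <- 2 * colSums(gsub_ != "NN")
    q_hat <- (n_a + 1) / (n_tot + 2)
    lod <- homozygosity_lod(geno$genotypes[aff, , drop = FALSE], q_hat,
                            error_rate = prm$lod_error_rate)
    peak <- which.max(lod$lod)
    list(candidate_interval = overlap$interval,
         candidate_kb = interval_length_kb(overlap$interval),
         inconsistent_markers = overlap$inconsistent_markers,
         lod_max = max(lod$lod),
         lod_peak_marker = geno$markers$id[peak],
         lod_peak_pos = geno$markers$pos[peak],
         lod_peak_in_candidate = interval_contains(
           overlap$interval, geno$markers$chrom[peak],
           geno$markers$pos[peak]))
  })

  ## --- gene models + genome ------------------------------------------
  models <- run_stage("gene_model", {
    ids <- unique(read.table(pth("gene_models"), sep = "\t",
                             header = TRUE)$transcript_id)
    lapply(setNames(ids, ids), function(id)
      load_gene_model(pth("gene_models"), "gff", transcript = id))
  })
  genome <- run_stage("gene_model", read_genome_fasta(pth("genome")))
  focal_model <- models[[cfg$focal_transcript]]
  if (is.null(focal_model))
    stop("stage 'gene_model': focal transcript '", cfg$focal_transcript,
         "' not in ", pth("gene_models"))

  ## --- variant triage --------------------------------------------------
  triage <- run_stage("triage", {
    v <- read_variants_vcf(pth("variants"))
    v <- classify_variants(v, models, genome)
    v$rarity <- rare_filter(v[, af_columns(v), drop = FALSE],
                            threshold = prm$af_threshold)
    summ <- triage_summary(v, mapping$candidate_interval)
    list(variants = v, summary = summ)
  })

  ## --- retention -------------------------------------------------------
  retention <- run_stage("retention", {
    reads <- read_reads_tsv(pth("reads"))
    counts <- count_junctions(reads, focal_model,
                              min_anchor = prm$min_anchor)
    pg <- counts$per_group
    est <- cbind(pg[, c("intron", "group")],
                 retention_estimate(pg$spanning, pg$spliced))
    ## focal intron = top retention hit by affected-minus-control contrast
    wide <- split(est, est$intron)
    contrast <- vapply(wide, function(d) {
      a <- d$proportion[d$group == "affected"]
      c0 <- d$proportion[d$group == "control"]
      if (!length(a) || !length(c0)) return(NA_real_)
      a - c0
    }, numeric(1))
    top <- as.integer(names(which.max(contrast)))
    cmp <- compare_groups(pg[pg$intron == top, ])
    v <- cfg$variant
    het_samples <- unique(reads$sample_id[reads$genotype == "het"])
    bases <- reads$base_at_variant[reads$sample_id %in% het_samples]
    allelic <- allelic_association(bases, v$ref, v$alt)
    list(per_group = est, focal_intron = top, comparisons = cmp,
         allelic = allelic)
  })

  ## --- consequence -----------------------------------------------------
  consequence <- run_stage("consequence", {
    orf <- retained_intron_orf(focal_model, genome,
                               retention$focal_intron,
                               rule_nt = prm$rule_nt)
    amp <- amplicon_lengths(focal_model, retention$focal_intron,
                            as_interval(cfg$primers$fwd),
                            as_interval(cfg$primers$rev))
    list(orf = unclass(orf)[c("intron", "premature_stop", "stop_offset_bp",
                              "mutant_protein_len", "wildtype_protein_len",
                              "aberrant_residues", "nmd_predicted")],
         amplicons = amp)
  })

  ## --- RT-PCR / qPCR ---------------------------------------------------
  splice_quant <- run_stage("rtpcr", {
    areas <- read_quant_tsv(pth("areas"))
    ct <- read_quant_tsv(pth("ct"))
    gs <- group_summary(areas)
    rel <- ddct_relative(ct, reference_group = prm$reference_group)
    list(summary = gs$summary, comparisons = gs$comparisons, relative = rel)
  })

  report <- list(
    mapping = c(mapping[setdiff(names(mapping), "candidate_interval")],
                list(candidate_interval =
                       mapping$candidate_interval[c("chrom", "start", "end")])),
    triage = list(table = as.data.frame.matrix(triage$summary$table),
                  n_rare_noncoding = triage$summary$n_rare_noncoding,
                  n_rare_intronic = triage$summary$n_rare_intronic,
                  n_rare_intergenic = triage$summary$n_rare_intergenic,
                  n_rare_coding_or_splice =
                    triage$summary$n_rare_coding_or_splice),
    retention = retention,
    consequence = consequence,
    splice_quant = splice_quant,
    provenance = list(package_version = as.character(packageVersion("rohsplice")),
                      config_hash = cfg_hash, seed = cfg$seed))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(retention$per_group, file.path(outdir, "retention.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(retention$comparisons, file.path(outdir, "comparisons.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(triage$variants, file.path(outdir, "triage.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(report))
  }
  report
}
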