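#' Cohort specification for the genotype generator
#'
#' Describes a consanguineous-pedigree cohort: affected individuals share an
#' autozygous founder segment around the disease locus; parents carry one
#' founder haplotype there; controls follow Hardy-Weinberg everywhere.
#' Defaults mirror a study design of 7 affecteds and 15 unaffected parents
#' genotyped on a dense SNP array, with the shared segment placed at the
#' disease region of homozygosity on chr21.
#'
#' @param n_affected,n_parents,n_controls sample counts.
#' @param marker_count number of markers on the (single-chromosome) map.
#' @param q allele-A frequency per marker (scalar or vector), strictly in
#'   (0, 1).
#' @param error_rate genotyping error rate: probability an autozygous
#'   homozygous call is read as heterozygous.
#' @param segment [genomic_interval()]: the autozygous core segment shared by
#'   all affecteds.
#' @param map [genomic_interval()]: the marker map extent.
#' @param extend_kb_max each affected's own autozygous segment extends beyond
#'   the shared core by Uniform(0, `extend_kb_max`) kb on each side.
#' @param missing_rate per-call probability of a missing (`NN`) call.
#' @param seed integer seed (required).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_affected = 7, n_parents = 15, n_controls = 10,
                        marker_count = 2000, q = 0.35, error_rate = 0.005,
                        segment = genomic_interval("chr21", 33364965, 34029433),
                        map = genomic_interval("chr21", 31000000, 36000000),
                        extend_kb_max = 300, missing_rate = 0.01, seed) {
  if (any(q <= 0 | q >= 1)) stop("q must be strictly in (0, 1)")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  if (segment$start < map$start || segment$end > map$end)
    stop("autozygous segment outside the marker map")
  structure(list(n_affected = n_affected, n_parents = n_parents,
                 n_controls = n_controls, marker_count = marker_count,
                 q = q, error_rate = error_rate, segment = segment,
                 map = map, extend_kb_max = extend_kb_max,
                 missing_rate = missing_rate, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic SNP genotype table with truth ROH segments
#'
#' Affected individuals are homozygous for a founder haplotype across the
#' seeded autozygous segment (each with private random extension), except
#' for `error_rate` heterozygous miscalls; all other calls are
#' Hardy-Weinberg draws at the marker's allele frequency. The generator
#' returns its latent truth (per-individual autozygous intervals and founder
#' alleles) for recovery testing.
#'
#' @param spec a [cohort_spec()].
#' @return list with `genotypes` (character matrix samples x markers),
#'   `samples` (data.frame `id`, `role`), `markers` (data.frame `id`,
#'   `chrom`, `pos`, `q`), `truth` (data.frame `individual`, `start`, `end`:
#'   marker-delimited autozygous interval per affected) and `founder`
#'   (character vector of founder alleles per marker).
#' @export
gen_genotypes <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    m <- spec$marker_count
    q <- rep_len(spec$q, m)
    pos <- round(seq(spec$map$start, spec$map$end, length.out = m))
    markers <- data.frame(id = sprintf("rs%06d", seq_len(m)),
                          chrom = spec$map$chrom, pos = pos, q = q)
    founder <- ifelse(runif(m) < q, "A", "B")

    hwe_draw <- function(n) {
      u <- runif(n)
      ifelse(u < q^2, "AA", ifelse(u < q^2 + 2 * q * (1 - q), "AB", "BB"))
    }
    ids <- c(sprintf("aff%02d", seq_len(spec$n_affected)),
             sprintf("par%02d", seq_len(spec$n_parents)),
             sprintf("ctl%02d", seq_len(spec$n_controls)))
    roles <- rep(c("affected", "parent", "control"),
                 c(spec$n_affected, spec$n_parents, spec$n_controls))
    g <- matrix(NA_character_, nrow = length(ids), ncol = m,
                dimnames = list(ids, markers$id))
    truth <- data.frame(individual = character(0), start = numeric(0),
                        end = numeric(0))
    for (i in seq_along(ids)) {
      row <- hwe_draw(m)
      if (roles[i] == "affected") {
        lo <- spec$segment$start - runif(1, 0, spec$extend_kb_max * 1000)
        hi <- spec$segment$end + runif(1, 0, spec$extend_kb_max * 1000)
        inside <- pos >= lo & pos <= hi
        row[inside] <- paste0(founder[inside], founder[inside])
        err <- inside & runif(m) < spec$error_rate
        row[err] <- "AB"
        truth <- rbind(truth, data.frame(
          individual = ids[i], start = min(pos[inside]),
          end = max(pos[inside])))
      } else if (roles[i] == "parent") {
        ## one founder haplotype over the shared core; other allele random
        inside <- pos >= spec$segment$start & pos <= spec$segment$end
        other <- ifelse(runif(m) < q, "A", "B")
        pair <- paste0(pmin(founder, other), pmax(founder, other))
        row[inside] <- pair[inside]
      }
      row[runif(m) < spec$missing_rate] <- "NN"
      g[i, ] <- row
    }
    list(genotypes = g,
         samples = data.frame(id = ids, role = roles),
         markers = markers, truth = truth, founder = founder)
  })
}

#' Write a genotype table as PED-like TSVs
#'
#' `genotypes.tsv` holds one row per sample (`sample_id`, `role`, one column
#' per marker); `markers.tsv` holds the marker map.
#'
#' @param cohort result of [gen_genotypes()].
#' @param genotype_path,marker_path output paths.
#' @return invisible list of the two paths.
#' @export
write_genotypes_tsv <- function(cohort, genotype_path, marker_path) {
  gt <- data.frame(sample_id = rownames(cohort$genotypes),
                   role = cohort$samples$role,
                   cohort$genotypes, check.names = FALSE)
  write.table(gt, genotype_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$markers, marker_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(genotypes = genotype_path, markers = marker_path))
}

#' Read genotype TSVs written by [write_genotypes_tsv()]
#' @param genotype_path,marker_path input paths.
#' @return list with `genotypes`, `samples`, `markers` (no truth).
#' @export
read_genotypes_tsv <- function(genotype_path, marker_path) {
  gt <- read.table(genotype_path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  markers <- read.table(marker_path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  g <- as.matrix(gt[, !(names(gt) %in% c("sample_id", "role")), drop = FALSE])
  rownames(g) <- gt$sample_id
  list(genotypes = g,
       samples = data.frame(id = gt$sample_id, role = gt$role),
       markers = markers)
}
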