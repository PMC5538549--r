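#' Generate a synthetic variant fixture (VCF + truth labels)
#'
#' Places, by construction, exactly `n_rare_intronic` rare intronic variants
#' (always including the focal splice-region variant of the disease-gene
#' fixture) and `n_rare_intergenic` rare intergenic variants inside the
#' region of homozygosity, zero rare coding or canonical-splice variants
#' inside it, plus configurable common variants inside the ROH and rare
#' coding variants in a bystander gene outside it. Each record carries
#' per-database `AF_DB*` INFO frequencies: rare variants are below the 1%
#' filter in every database (or absent), common variants at or above it in
#' at least one.
#'
#' @param seed integer seed.
#' @param gene disease-gene fixture from [synthetic_gene_model()].
#' @param bystander coding-variant host gene from
#'   [synthetic_bystander_gene()].
#' @param roh the region-of-homozygosity [genomic_interval()].
#' @param n_rare_intronic,n_rare_intergenic,n_common,n_rare_coding_outside
#'   variant counts per class.
#' @param n_db number of population databases (INFO keys `AF_DB1..`).
#' @return list with `variants` (data.frame `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `AF_DB*` columns), `truth` (data.frame `pos`, `class`, `rarity`,
#'   `in_roh`), `roh`, `gene`, `bystander`.
#' @export
gen_variant_fixture <- function(seed,
                                gene = synthetic_gene_model(),
                                bystander = synthetic_bystander_gene(),
                                roh = genomic_interval("chr21", 33364965,
                                                       34029433),
                                n_rare_intronic = 18,
                                n_rare_intergenic = 20,
                                n_common = 25,
                                n_rare_coding_outside = 5,
                                n_db = 4) {
  with_seed(seed, {
    model <- gene$model
    span <- gene_span(model)
    focal <- gene$variant

    ## candidate intronic positions: all intron bases more than 2 bp from
    ## any junction (so they triage as intronic, never canonical splice)
    intronic_pool <- unlist(lapply(seq_len(nrow(model$introns)), function(k) {
      s <- model$introns$start[k]; e <- model$introns$end[k]
      seq(s + 2, e - 2)
    }))
    intronic_pool <- setdiff(intronic_pool, focal$pos)
    if (n_rare_intronic - 1 > length(intronic_pool))
      stop("requested rare intronic count exceeds available intron positions")
    pos_intronic <- if (n_rare_intronic == 0) numeric(0) else
      c(focal$pos, sort(sample(intronic_pool, n_rare_intronic - 1)))

    ## intergenic: inside the ROH, outside the gene span
    intergenic_pool_n <- (span$start - roh$start) + (roh$end - span$end)
    if (n_rare_intergenic + n_common > intergenic_pool_n)
      stop("requested counts exceed available intergenic positions")
    draw_intergenic <- function(n, taken) {
      out <- numeric(0)
      while (length(out) < n) {
        p <- round(runif(n, roh$start, roh$end))
        p <- p[p < span$start | p > span$end]
        out <- unique(c(out, setdiff(p, taken)))
      }
      sort(out[seq_len(n)])
    }
    pos_intergenic <- draw_intergenic(n_rare_intergenic, pos_intronic)
    pos_common <- draw_intergenic(n_common, c(pos_intronic, pos_intergenic))

    ## rare coding variants outside the ROH, in the bystander CDS
    bm <- bystander$model
    pos_coding <- if (n_rare_coding_outside == 0) numeric(0) else
      sort(cds_to_genomic(bm, sample(seq_len(cds_length(bm)),
                                     n_rare_coding_outside)))

    ref_at <- function(pos, genome) {
      vapply(pos, function(p) {
        r <- tryCatch(genome_fetch(genome, "chr21", p, p), error = function(e) NA)
        if (is.na(r)) sample(BASES, 1) else r
      }, character(1))
    }
    alt_for <- function(ref) vapply(ref, function(r)
      sample(setdiff(BASES, r), 1), character(1))

    rare_afs <- function(n) {
      af <- matrix(runif(n * n_db, 0, 0.005), nrow = n, ncol = n_db)
      af[matrix(runif(n * n_db) < 0.5, nrow = n, ncol = n_db)] <- NA  # absent
      af
    }
    common_afs <- function(n) {
      af <- matrix(runif(n * n_db, 0, 0.009), nrow = n, ncol = n_db)
      hit <- sample.int(n_db, n, replace = TRUE)
      af[cbind(seq_len(n), hit)] <- runif(n, 0.01, 0.3)
      af
    }

    build <- function(pos, genome, class, rarity, af) {
      af <- as.data.frame(af)
      names(af) <- paste0("AF_DB", seq_len(n_db))
      if (!length(pos))
        return(cbind(data.frame(chrom = character(0), pos = numeric(0),
                                id = character(0), ref = character(0),
                                alt = character(0), class = character(0),
                                rarity = character(0)), af[0, , drop = FALSE]))
      ref <- ref_at(pos, genome)
      cbind(data.frame(chrom = "chr21", pos = pos, id = ".",
                       ref = ref, alt = alt_for(ref),
                       class = class, rarity = rarity,
                       stringsAsFactors = FALSE), af)
    }
    vi <- build(pos_intronic, gene$genome, "intronic", "rare",
                rare_afs(length(pos_intronic)))
    if (nrow(vi)) {  # pin the focal record to its known substitution
      vi$ref[1] <- focal$ref; vi$alt[1] <- focal$alt
    }
    vg <- build(pos_intergenic, list(), "intergenic", "rare",
                rare_afs(n_rare_intergenic))
    vc <- build(pos_common, list(), "intergenic", "common",
                common_afs(n_common))
    vb <- build(pos_coding, bystander$genome, "coding", "rare",
                rare_afs(n_rare_coding_outside))
    all <- rbind(vi, vg, vc, vb)
    all <- all[order(all$pos), , drop = FALSE]
    rownames(all) <- NULL

    truth <- data.frame(pos = all$pos, class = all$class,
                        rarity = all$rarity,
                        in_roh = interval_contains(roh, all$chrom, all$pos))
    variants <- all[, c("chrom", "pos", "id", "ref", "alt",
                        paste0("AF_DB", seq_len(n_db)))]
    list(variants = variants, truth = truth, roh = roh, gene = gene,
         bystander = bystander)
  })
}

#' Write a variant fixture as VCF 4.2
#' @param fixture result of [gen_variant_fixture()], or any data.frame with
#'   `chrom`, `pos`, `id`, `ref`, `alt` and `AF_*` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(fixture, path) {
  v <- if (is.data.frame(fixture)) fixture else fixture$variants
  afc <- af_columns(v)
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=chr21>",
              vapply(afc, function(k) sprintf(
                "##INFO=<ID=%s,Number=1,Type=Float,Description=\"Allele frequency in database %s\">",
                k, sub("^AF_", "", k)), character(1)),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(v)), function(i) {
    vals <- unlist(v[i, afc])
    keep <- !is.na(vals)
    if (!any(keep)) return(".")
    paste(sprintf("%s=%s", afc[keep],
                  formatC(vals[keep], digits = 6, format = "g")),
          collapse = ";")
  }, character(1))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                  v$chrom, as.integer(v$pos), v$id, v$ref, v$alt, info)
  writeLines(c(header, body), path)
  invisible(path)
}
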