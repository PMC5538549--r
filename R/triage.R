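TRIAGE_CATEGORIES <- c("nonsynonymous_coding", "synonymous_coding",
                       "canonical_splice", "utr", "intronic", "intergenic")

#' Read a VCF of variants with per-database allele frequencies
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) whose INFO field carries
#' `AF_<db>=<frequency>` keys, one per population database. Absent keys are
#' returned as `NA` (treated as frequency 0 by [rare_filter()]).
#'
#' @param path VCF path.
#' @return data.frame with `chrom`, `pos`, `id`, `ref`, `alt` and one numeric
#'   `AF_*` column per database seen in the file.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- if (nrow(fix)) v@fix[, "INFO"] else character(0)
  out <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                    id = fix$ID, ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  ## collect all AF_* keys present anywhere in the file
  kv <- lapply(strsplit(info, ";", fixed = TRUE), function(fields) {
    fields <- fields[grepl("^AF_[^=]+=", fields)]
    if (!length(fields)) return(character(0))
    setNames(sub("^[^=]+=", "", fields), sub("=.*$", "", fields))
  })
  keys <- sort(unique(unlist(lapply(kv, names))))
  for (k in keys)
    out[[k]] <- as.numeric(vapply(kv, function(x) x[k] %||% NA_character_,
                                  character(1)))
  out
}

af_columns <- function(variants) grep("^AF_", names(variants), value = TRUE)

## classify one position against one model; returns list(category, distance)
classify_one <- function(pos, alt, model, genome = NULL) {
  span <- gene_span(model)
  if (pos < span$start || pos > span$end)
    return(list(category = "intergenic", distance = NA_real_))
  e <- exon_index_of(model, pos)
  if (!is.na(e)) {
    cpos <- genomic_to_cds(model, pos)
    if (is.na(cpos)) return(list(category = "utr", distance = NA_real_))
    if (is.null(genome))
      stop("coding variant at ", pos, " but no genome sequence supplied")
    cseq <- cds_seq(model, genome)
    ci <- ceiling(cpos / 3)
    within <- cpos - (ci - 1) * 3
    wt_codon <- substr(cseq, (ci - 1) * 3 + 1, ci * 3)
    tx_alt <- if (model$strand == "-") complement_base(alt) else alt
    mut_codon <- wt_codon
    substr(mut_codon, within, within) <- tx_alt
    cat <- if (translate_dna(wt_codon) == translate_dna(mut_codon))
      "synonymous_coding" else "nonsynonymous_coding"
    return(list(category = cat, distance = NA_real_))
  }
  j <- intron_index_of(model, pos)
  irow <- model$introns[model$introns$intron == j, ]
  ## signed distance: positive = downstream of the donor, negative =
  ## upstream of the acceptor (intronic side), nearest junction wins
  if (model$strand == "+") {
    d_donor <- pos - irow$start + 1
    d_acceptor <- -(irow$end - pos + 1)
  } else {
    d_donor <- irow$end - pos + 1
    d_acceptor <- -(pos - irow$start + 1)
  }
  d <- if (abs(d_donor) <= abs(d_acceptor)) d_donor else d_acceptor
  cat <- if (abs(d) <= 2) "canonical_splice" else "intronic"
  list(category = cat, distance = d)
}

#' Classify variants against gene models (Table-style categories)
#'
#' Each variant receives exactly one category among `nonsynonymous_coding`,
#' `synonymous_coding`, `canonical_splice` (within 2 bp of the intron-exon
#' junction on the intronic side), `utr`, `intronic`, `intergenic`.
#' Precedence is coding > canonical splice > UTR > intronic > intergenic;
#' with several transcripts the most severe call wins.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` (multi-base
#'   events are classified by their leftmost affected base).
#' @param models a [gene_model()] or list of them.
#' @param genome list of [seq_segment()] covering the models' CDS (needed to
#'   split coding variants into synonymous/nonsynonymous).
#' @return the input data.frame with added `category` (factor over the six
#'   categories) and `distance_to_junction` (signed bp, intronic variants
#'   only: negative toward the acceptor).
#' @export
classify_variants <- function(variants, models, genome = NULL) {
  if (inherits(models, "gene_model")) models <- list(models)
  n <- nrow(variants)
  category <- character(n)
  distance <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    calls <- lapply(models, function(m) {
      if (m$chrom != variants$chrom[i])
        list(category = "intergenic", distance = NA_real_)
      else classify_one(variants$pos[i], substr(variants$alt[i], 1, 1),
                        m, genome)
    })
    sev <- vapply(calls, function(x) match(x$category, TRIAGE_CATEGORIES),
                  numeric(1))
    best <- calls[[which.min(sev)]]
    category[i] <- best$category
    distance[i] <- best$distance
  }
  variants$category <- factor(category, levels = TRIAGE_CATEGORIES)
  variants$distance_to_junction <- distance
  variants
}

#' Rare-variant frequency filter
#'
#' A variant is `common` iff its allele frequency is at or above `threshold`
#' in *any* population database (the inclusive ">= 1% in any" rule);
#' frequencies absent from a database are treated as 0, so a never-observed
#' variant is rare.
#'
#' @param af numeric vector, matrix or data.frame of per-database allele
#'   frequencies (rows = variants); `NA` = absent.
#' @param threshold frequency cutoff (default 0.01).
#' @return character vector `"rare"`/`"common"`, one per variant.
#' @export
rare_filter <- function(af, threshold = 0.01) {
  if (is.data.frame(af)) af <- as.matrix(af)
  if (!is.matrix(af)) af <- matrix(af, nrow = 1)
  mode(af) <- "numeric"
  if (any(af < 0, na.rm = TRUE)) stop("negative allele frequency")
  af[is.na(af)] <- 0
  if (ncol(af) == 0) return(rep("rare", nrow(af)))
  ifelse(apply(af >= threshold, 1, any), "common", "rare")
}

#' Summarize triaged variants inside a candidate interval
#'
#' Builds the category-by-rarity contingency table for variants inside the
#' interval and the noncoding rollup the discovery analysis keys on:
#' `n_rare_noncoding = rare intronic + rare intergenic` (UTR variants are
#' counted separately).
#'
#' @param variants data.frame from [classify_variants()] with a `rarity`
#'   column (from [rare_filter()]).
#' @param interval a [genomic_interval()] (e.g. the minimal ROH).
#' @return object of class `triage_summary`: list with `table` (6 x 2
#'   category-by-rarity matrix), `n_rare_noncoding`, `n_rare_intronic`,
#'   `n_rare_intergenic`, `n_rare_coding_or_splice` and `interval`.
#' @export
triage_summary <- function(variants, interval) {
  stopifnot(inherits(interval, "genomic_interval"),
            all(c("category", "rarity") %in% names(variants)))
  inside <- variants[interval_contains(interval, variants$chrom,
                                       variants$pos), , drop = FALSE]
  tab <- table(category = factor(inside$category, levels = TRIAGE_CATEGORIES),
               rarity = factor(inside$rarity, levels = c("rare", "common")))
  structure(list(
    table = unclass(tab),
    n_rare_intronic = tab["intronic", "rare"],
    n_rare_intergenic = tab["intergenic", "rare"],
    n_rare_noncoding = tab["intronic", "rare"] + tab["intergenic", "rare"],
    n_rare_coding_or_splice = tab["nonsynonymous_coding", "rare"] +
      tab["synonymous_coding", "rare"] + tab["canonical_splice", "rare"],
    interval = interval), class = "triage_summary")
}

#' @export
print.triage_summary <- function(x, ...) {
  cat(sprintf("<triage_summary> %s:%s-%s\n", x$interval$chrom,
              format(x$interval$start, big.mark = ","),
              format(x$interval$end, big.mark = ",")))
  print(x$table)
  cat(sprintf("rare noncoding (intronic + intergenic): %d\n",
              x$n_rare_noncoding))
  invisible(x)
}
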