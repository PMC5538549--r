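#' Parse simplified CIGAR strings into aligned blocks
#'
#' Only match (`M`) and skipped-intron (`N`) operations are supported; the
#' junction-read TSV emitted by [gen_junction_reads()] uses exactly these.
#'
#' @param pos 1-based leftmost aligned genomic position per read.
#' @param cigar character vector of CIGAR strings, e.g. `"47M109N53M"`.
#' @return data.frame in long form: `read` (index into the input), `start`,
#'   `end` of each aligned (M) block, in genomic order.
#' @export
cigar_blocks <- function(pos, cigar) {
  stopifnot(length(pos) == length(cigar))
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z]", cigar))
  bad <- vapply(toks, function(t) !length(t) ||
                  any(!grepl("[MN]$", t)), logical(1)) |
    nchar(cigar) != vapply(toks, function(t) sum(nchar(t)), numeric(1))
  if (any(bad))
    stop("malformed CIGAR (only M and N supported): ",
         paste(unique(cigar[bad]), collapse = ", "))
  out <- vector("list", length(pos))
  for (i in seq_along(pos)) {
    len <- as.numeric(sub("[MN]$", "", toks[[i]]))
    op <- sub("^[0-9]+", "", toks[[i]])
    ends <- pos[i] - 1 + cumsum(len)
    starts <- ends - len + 1
    keep <- op == "M"
    out[[i]] <- cbind(read = i, start = starts[keep], end = ends[keep])
  }
  as.data.frame(do.call(rbind, out))
}

#' Classify reads relative to one intron
#'
#' Implements the junction-evidence counting rule behind the retention
#' estimator: a read is `spanning` iff a contiguous aligned block covers an
#' intron boundary (donor or acceptor) with at least `min_anchor` aligned
#' bases on both sides of it and no splice gap at that boundary; `spliced`
#' iff the alignment contains a gap whose coordinates exactly equal the
#' intron, with at least `min_anchor` anchor bases on both flanking exons;
#' otherwise `uninformative` (including reads wholly inside the intron).
#'
#' @param reads data.frame with `pos` and `cigar` columns (and usually
#'   `chrom`, checked against the model when present).
#' @param model a [gene_model()].
#' @param intron intron number.
#' @param min_anchor minimum aligned bases on each side of a junction
#'   (default 6).
#' @return character vector `"spanning"`/`"spliced"`/`"uninformative"`.
#' @export
classify_reads <- function(reads, model, intron, min_anchor = 6) {
  stopifnot(intron %in% model$introns$intron)
  irow <- model$introns[model$introns$intron == intron, ]
  s <- irow$start; e <- irow$end
  n <- nrow(reads)
  if (!n) return(character(0))
  on_chrom <- if ("chrom" %in% names(reads)) reads$chrom == model$chrom
              else rep(TRUE, n)
  bl <- cigar_blocks(reads$pos, reads$cigar)
  len <- bl$end - bl$start + 1

  ## spanning: a block straddles boundary (s-1|s) or (e|e+1) with anchors
  span_block <- (bl$start <= s - min_anchor & bl$end >= s + min_anchor - 1) |
                (bl$start <= e - min_anchor + 1 & bl$end >= e + min_anchor)
  spanning <- tabulate(bl$read[span_block], nbins = n) > 0

  ## spliced: consecutive blocks of one read with gap == [s, e]
  same_read <- bl$read[-1] == bl$read[-nrow(bl)]
  gap_lo <- bl$end[-nrow(bl)] + 1
  gap_hi <- bl$start[-1] - 1
  splice_pair <- same_read & gap_lo == s & gap_hi == e &
    len[-nrow(bl)] >= min_anchor & len[-1] >= min_anchor
  spliced <- tabulate(bl$read[-nrow(bl)][splice_pair], nbins = n) > 0

  out <- rep("uninformative", n)
  out[spliced] <- "spliced"
  out[spanning] <- "spanning"   # mutually exclusive by construction
  out[!on_chrom] <- "uninformative"
  out
}

#' Count junction-informative reads per intron, sample and genotype group
#'
#' Each read is counted at most once per intron (a read spanning both the
#' donor and acceptor of a retained intron contributes one spanning count).
#' Pooled group counts are sums over member samples, mirroring
#' pool-then-test quantification.
#'
#' @param reads data.frame with `pos`, `cigar`, `sample_id` and either a
#'   `group` column or a `groups` named vector mapping sample to group.
#' @param model a [gene_model()].
#' @param groups optional named character vector `sample_id -> group`.
#' @param min_anchor see [classify_reads()].
#' @return list with `per_sample` and `per_group` data.frames, columns
#'   `intron`, `sample`/`group`, `spanning`, `spliced`.
#' @export
count_junctions <- function(reads, model, groups = NULL, min_anchor = 6) {
  if (is.null(groups)) {
    if (!"group" %in% names(reads))
      stop("either a 'group' column or a 'groups' mapping is required")
    groups <- tapply(as.character(reads$group), reads$sample_id,
                     function(g) g[1])
  }
  samples <- sort(unique(as.character(reads$sample_id)))
  introns_all <- model$introns$intron
  if (!length(samples)) {
    per_group <- expand.grid(intron = introns_all,
                             group = sort(unique(unname(groups))),
                             stringsAsFactors = FALSE)
    per_group$spanning <- 0L
    per_group$spliced <- 0L
    return(list(per_sample = data.frame(intron = integer(0),
                                        sample = character(0),
                                        spanning = integer(0),
                                        spliced = integer(0),
                                        group = character(0)),
                per_group = per_group))
  }
  if (any(!samples %in% names(groups)))
    stop("samples with no group label: ",
         paste(setdiff(samples, names(groups)), collapse = ", "))
  introns <- model$introns$intron
  per_sample <- do.call(rbind, lapply(introns, function(i) {
    cls <- classify_reads(reads, model, i, min_anchor)
    sp <- table(factor(reads$sample_id[cls == "spanning"], levels = samples))
    sl <- table(factor(reads$sample_id[cls == "spliced"], levels = samples))
    data.frame(intron = i, sample = samples,
               spanning = as.integer(sp), spliced = as.integer(sl))
  }))
  if (is.null(per_sample) || !nrow(per_sample)) {
    per_group <- expand.grid(intron = introns,
                             group = sort(unique(unname(groups))),
                             stringsAsFactors = FALSE)
    per_group$spanning <- 0L
    per_group$spliced <- 0L
    return(list(per_sample = data.frame(intron = integer(0),
                                        sample = character(0),
                                        spanning = integer(0),
                                        spliced = integer(0),
                                        group = character(0)),
                per_group = per_group))
  }
  per_sample$group <- unname(groups[per_sample$sample])
  per_group <- aggregate(cbind(spanning, spliced) ~ intron + group,
                         data = per_sample, FUN = sum)
  per_group$group <- as.vector(per_group$group)
  per_group <- per_group[order(per_group$intron, per_group$group), ]
  rownames(per_group) <- NULL
  list(per_sample = per_sample, per_group = per_group)
}

#' Intron-retention proportion with 95% confidence interval
#'
#' The retention estimate is `R = spanning / (spanning + spliced)` over
#' junction-informative reads. The default interval is the Wilson score
#' interval; Clopper-Pearson is available. With zero informative reads the
#' estimate is undefined and reported as `NA` (never as 0).
#'
#' @param spanning,spliced non-negative counts (vectorized).
#' @param conf confidence level (default 0.95).
#' @param method `"wilson"` or `"clopper-pearson"`.
#' @return data.frame with `spanning`, `spliced`, `proportion`, `ci_low`,
#'   `ci_high`.
#' @examples
#' retention_estimate(66, 34)$proportion  # 0.66
#' @export
retention_estimate <- function(spanning, spliced, conf = 0.95,
                               method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  stopifnot(length(spanning) == length(spliced),
            all(spanning >= 0), all(spliced >= 0))
  n <- spanning + spliced
  p <- ifelse(n > 0, spanning / n, NA_real_)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "wilson") {
    denom <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- pmax(0, center - half)
    hi <- pmin(1, center + half)
  } else {
    lo <- hi <- rep(NA_real_, length(n))
    for (i in seq_along(n)) {
      if (is.na(p[i])) next
      ci <- stats::binom.test(spanning[i], n[i], conf.level = conf)$conf.int
      lo[i] <- ci[1]; hi[i] <- ci[2]
    }
  }
  lo[is.na(p)] <- NA_real_; hi[is.na(p)] <- NA_real_
  data.frame(spanning = spanning, spliced = spliced, proportion = p,
             ci_low = lo, ci_high = hi)
}

#' All pairwise group comparisons of retention counts
#'
#' Two-sided Fisher's exact test on each 2x2 `[spanning, spliced]` x
#' `[group A, group B]` table, with Holm step-down adjustment over the
#' pairwise family.
#'
#' @param group_counts data.frame with `group`, `spanning`, `spliced` (one
#'   row per group; e.g. the `per_group` rows of [count_junctions()] for one
#'   intron).
#' @return data.frame with `group1`, `group2`, the four counts, `p` (raw two
#'   sided) and `p_holm`.
#' @export
compare_groups <- function(group_counts) {
  stopifnot(all(c("group", "spanning", "spliced") %in% names(group_counts)))
  if (any(group_counts$spanning + group_counts$spliced == 0))
    stop("group with zero informative reads: ",
         paste(group_counts$group[group_counts$spanning +
                                    group_counts$spliced == 0],
               collapse = ", "))
  k <- nrow(group_counts)
  if (k < 2) stop("need at least two groups to compare")
  pairs <- combn(k, 2)
  res <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tab <- matrix(c(group_counts$spanning[a], group_counts$spliced[a],
                    group_counts$spanning[b], group_counts$spliced[b]),
                  nrow = 2)
    data.frame(group1 = group_counts$group[a],
               group2 = group_counts$group[b],
               spanning1 = tab[1, 1], spliced1 = tab[2, 1],
               spanning2 = tab[1, 2], spliced2 = tab[2, 2],
               p = stats::fisher.test(tab)$p.value)
  }))
  res$p_holm <- stats::p.adjust(res$p, method = "holm")
  res
}

#' Allele-specific retention association at the variant position
#'
#' Counts reads by the base they carry at the (intronic) variant position
#' and tests the mutant-base fraction against the 50% expected under no
#' association between retention and the mutant allele, by two-sided exact
#' binomial test.
#'
#' @param bases character vector of observed bases at the variant position,
#'   one per covering read (`NA` entries are dropped).
#' @param ref,alt reference and mutant base.
#' @return list with `n_mut`, `n_ref`, `n_other` (bases excluded from the
#'   test), `fraction` (mutant / (mutant + reference)) and `p`.
#' @export
allelic_association <- function(bases, ref, alt) {
  bases <- bases[!is.na(bases)]
  if (!length(bases)) stop("no reads cover the variant position")
  n_mut <- sum(bases == alt)
  n_ref <- sum(bases == ref)
  n_other <- length(bases) - n_mut - n_ref
  if (n_mut + n_ref == 0)
    stop("no reads carry the reference or mutant base")
  list(n_mut = n_mut, n_ref = n_ref, n_other = n_other,
       fraction = n_mut / (n_mut + n_ref),
       p = stats::binom.test(n_mut, n_mut + n_ref, 0.5)$p.value)
}

#' Fragments per kilobase of exonic length per million mapped fragments
#' @param fragments fragment count assigned to the gene.
#' @param exonic_length_bp total exonic length in bp (> 0).
#' @param total_fragments total mapped fragments in the library (> 0).
#' @return FPKM value(s).
#' @examples
#' fpkm(1000, 2000, 1e7)  # 50
#' @export
fpkm <- function(fragments, exonic_length_bp, total_fragments) {
  if (any(exonic_length_bp <= 0)) stop("exonic length must be positive")
  if (any(total_fragments <= 0)) stop("total mapped fragments must be positive")
  if (any(fragments < 0)) stop("fragment count must be non-negative")
  fragments / ((exonic_length_bp / 1000) * (total_fragments / 1e6))
}
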