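#' Gene model: exon/CDS structure of one transcript
#'
#' The coordinate frame for read classification, variant triage and
#' consequence prediction. Exons are supplied in *transcript* order: on the
#' plus strand that is increasing genomic coordinate, on the minus strand
#' decreasing. Introns are derived between consecutive exons and numbered
#' `1..n-1` in transcript order, so "intron 6" of a minus-strand gene sits at
#' *higher* genomic coordinates than exon 7, matching HGVS `c.X-k` semantics.
#'
#' @param transcript_id transcript name.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (1-based inclusive
#'   genomic), rows in transcript order.
#' @param cds_start genomic position of the first base of the start codon.
#' @param cds_end genomic position of the last base of the stop codon.
#' @return an object of class `gene_model` with derived `introns`
#'   (data.frame `intron`, `start`, `end`).
#' @export
gene_model <- function(transcript_id, chrom, strand, exons, cds_start, cds_end) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(chrom), length(chrom) == 1L,
            strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            nrow(exons) >= 1L)
  exons <- data.frame(start = as.numeric(exons$start),
                      end = as.numeric(exons$end))
  if (any(exons$start > exons$end)) stop("exon with start > end")
  n <- nrow(exons)
  ## transcript-order check + non-overlap
  if (n > 1L) {
    if (strand == "+") {
      if (any(diff(exons$start) <= 0) || any(exons$start[-1] <= exons$end[-n]))
        stop("exons overlap or are not in transcript order for strand '+'")
    } else {
      if (any(diff(exons$start) >= 0) || any(exons$end[-1] >= exons$start[-n]))
        stop("exons overlap or are not in transcript order for strand '-'")
    }
  }
  introns <- if (n > 1L) {
    if (strand == "+") {
      data.frame(intron = seq_len(n - 1L),
                 start = exons$end[-n] + 1, end = exons$start[-1] - 1)
    } else {
      data.frame(intron = seq_len(n - 1L),
                 start = exons$end[-1] + 1, end = exons$start[-n] - 1)
    }
  } else {
    data.frame(intron = integer(), start = numeric(), end = numeric())
  }
  if (nrow(introns) && any(introns$start > introns$end))
    stop("zero-length intron: adjacent exons are contiguous")
  m <- structure(list(transcript_id = transcript_id, chrom = chrom,
                      strand = strand, exons = exons, introns = introns,
                      cds_start = as.numeric(cds_start),
                      cds_end = as.numeric(cds_end)),
                 class = "gene_model")
  if (is.na(exon_index_of(m, m$cds_start)) || is.na(exon_index_of(m, m$cds_end)))
    stop("CDS boundary outside exons")
  t1 <- genomic_to_transcript(m, m$cds_start)
  t2 <- genomic_to_transcript(m, m$cds_end)
  if (t1 >= t2) stop("CDS start does not precede CDS end in transcript order")
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%s-%s (%s), %d exons, %d introns, CDS %d nt\n",
              x$transcript_id, x$chrom,
              format(gene_span(x)$start, big.mark = ","),
              format(gene_span(x)$end, big.mark = ","),
              x$strand, nrow(x$exons), nrow(x$introns), cds_length(x)))
  invisible(x)
}

#' Genomic span of a gene model
#' @param model a [gene_model()].
#' @return a [genomic_interval()] covering all exons and introns.
#' @export
gene_span <- function(model) {
  genomic_interval(model$chrom, min(model$exons$start), max(model$exons$end),
                   model$strand)
}

exon_lengths <- function(model) model$exons$end - model$exons$start + 1

#' Total exonic (mature transcript) length in bp
#' @param model a [gene_model()].
#' @return integer number of exonic bases.
#' @export
transcript_length <- function(model) as.integer(sum(exon_lengths(model)))

## index of the exon containing a genomic position, NA if intronic/outside
exon_index_of <- function(model, gpos) {
  hit <- which(model$exons$start <= gpos & gpos <= model$exons$end)
  if (length(hit)) hit[1] else NA_integer_
}

## index of the intron containing a genomic position, NA otherwise
intron_index_of <- function(model, gpos) {
  if (!nrow(model$introns)) return(NA_integer_)
  hit <- which(model$introns$start <= gpos & gpos <= model$introns$end)
  if (length(hit)) model$introns$intron[hit[1]] else NA_integer_
}

#' Convert genomic positions to transcript coordinates
#'
#' Transcript coordinate 1 is the first (5') base of exon 1. Intronic or
#' out-of-gene positions map to `NA`.
#'
#' @param model a [gene_model()].
#' @param gpos numeric vector of genomic positions.
#' @return numeric vector of transcript positions (NA where non-exonic).
#' @export
genomic_to_transcript <- function(model, gpos) {
  cum_before <- c(0, cumsum(exon_lengths(model)))[seq_len(nrow(model$exons))]
  vapply(gpos, function(g) {
    k <- exon_index_of(model, g)
    if (is.na(k)) return(NA_real_)
    off <- if (model$strand == "+") g - model$exons$start[k]
           else model$exons$end[k] - g
    cum_before[k] + off + 1
  }, numeric(1))
}

#' Convert transcript coordinates to genomic positions
#' @param model a [gene_model()].
#' @param tpos numeric vector of transcript positions in
#'   `1..transcript_length(model)`.
#' @return numeric vector of genomic positions.
#' @export
transcript_to_genomic <- function(model, tpos) {
  lens <- exon_lengths(model)
  cum <- cumsum(lens)
  cum_before <- c(0, cum)[seq_along(lens)]
  vapply(tpos, function(t) {
    if (is.na(t) || t < 1 || t > sum(lens)) return(NA_real_)
    k <- which(cum >= t)[1]
    off <- t - cum_before[k] - 1
    if (model$strand == "+") model$exons$start[k] + off
    else model$exons$end[k] - off
  }, numeric(1))
}

#' CDS length in nucleotides (start codon through stop codon)
#' @param model a [gene_model()].
#' @return integer CDS length.
#' @export
cds_length <- function(model) {
  as.integer(genomic_to_transcript(model, model$cds_end) -
             genomic_to_transcript(model, model$cds_start) + 1)
}

#' Convert CDS coordinates to genomic positions
#' @param model a [gene_model()].
#' @param cpos CDS positions (1 = first base of the start codon).
#' @return numeric vector of genomic positions.
#' @export
cds_to_genomic <- function(model, cpos) {
  t0 <- genomic_to_transcript(model, model$cds_start)
  bad <- cpos < 1 | cpos > cds_length(model)
  if (any(bad)) stop("CDS position outside CDS (1..", cds_length(model), ")")
  transcript_to_genomic(model, t0 + cpos - 1)
}

#' Convert genomic positions to CDS coordinates
#' @param model a [gene_model()].
#' @param gpos genomic positions.
#' @return CDS positions; `NA` when non-exonic or outside the CDS.
#' @export
genomic_to_cds <- function(model, gpos) {
  t0 <- genomic_to_transcript(model, model$cds_start)
  t <- genomic_to_transcript(model, gpos)
  c0 <- t - t0 + 1
  c0[!is.na(c0) & (c0 < 1 | c0 > cds_length(model))] <- NA_real_
  c0
}

## number of CDS bases 5' of intron i (the CDS offset at the donor boundary),
## clamped into [0, cds_length]
cds_bases_before_intron <- function(model, intron) {
  stopifnot(intron %in% model$introns$intron)
  cum <- cumsum(exon_lengths(model))
  t_donor <- cum[intron]                       # last transcript base of exon i
  t0 <- genomic_to_transcript(model, model$cds_start)
  max(0, min(cds_length(model), t_donor - t0 + 1))
}

#' Parse HGVS-style intronic cDNA notation
#'
#' Handles strings like `"c.1047-9A>G"` or `"c.100+1"`: a CDS anchor (the
#' boundary-adjacent exonic base), a signed intronic offset (negative =
#' upstream of an acceptor, positive = downstream of a donor), and an
#' optional transcript-strand substitution.
#'
#' @param x a single HGVS-like string.
#' @return list with `cds_anchor`, `offset`, and (possibly `NA`) `ref`, `alt`
#'   transcript-strand bases.
#' @export
parse_hgvs_intronic <- function(x) {
  m <- regmatches(x, regexec(
    "^c\\.([0-9]+)([+-])([0-9]+)(?:([ACGT])>([ACGT]))?$", x))[[1]]
  if (!length(m)) stop("cannot parse HGVS intronic notation: ", x)
  list(cds_anchor = as.integer(m[2]),
       offset = as.integer(m[4]) * if (m[3] == "-") -1L else 1L,
       ref = if (nzchar(m[5])) m[5] else NA_character_,
       alt = if (nzchar(m[6])) m[6] else NA_character_)
}

#' Resolve an HGVS intronic position to a genomic base
#'
#' Walks `|offset|` bases into the intron adjacent to the anchor exon,
#' respecting strand. For `c.1047-9` on a minus-strand gene whose exon 7
#' acceptor boundary is at genomic 33,582,055, the result is genomic
#' 33,582,064 in intron 6: "upstream of the acceptor" means *higher* genomic
#' coordinate on the minus strand.
#'
#' @param model a [gene_model()].
#' @param cds_anchor CDS coordinate of the boundary-adjacent exonic base.
#' @param offset signed intronic offset; negative offsets count from the
#'   acceptor of the preceding intron, positive from the donor of the
#'   following intron. Must be non-zero and within the intron length.
#' @return list with `interval` (single-base [genomic_interval()]), `intron`
#'   (intron number in transcript order) and `position` (genomic position).
#' @examples
#' fix <- synthetic_gene_model()
#' resolve_hgvs_intronic(fix$model, 1047, -9)$position  # 33582064
#' @export
resolve_hgvs_intronic <- function(model, cds_anchor, offset) {
  stopifnot(inherits(model, "gene_model"))
  stop_if_not_scalar_number(cds_anchor, "cds_anchor")
  stop_if_not_scalar_number(offset, "offset")
  if (offset == 0) stop("intronic offset must be non-zero")
  if (cds_anchor < 1 || cds_anchor > cds_length(model))
    stop("cds_anchor outside the CDS (1..", cds_length(model), ")")
  g <- cds_to_genomic(model, cds_anchor)
  e <- exon_index_of(model, g)
  t_anchor <- genomic_to_transcript(model, g)
  cum <- cumsum(exon_lengths(model))
  cum_before <- c(0, cum)[seq_len(nrow(model$exons))]
  n_ex <- nrow(model$exons)
  if (offset < 0) {
    if (e == 1L) stop("no intron upstream of exon 1")
    if (t_anchor != cum_before[e] + 1)
      stop("cds_anchor is not the first base of its exon; ",
           "negative offsets must anchor on the acceptor-adjacent base")
    intron <- e - 1L
  } else {
    if (e == n_ex) stop("no intron downstream of the last exon")
    if (t_anchor != cum[e])
      stop("cds_anchor is not the last base of its exon; ",
           "positive offsets must anchor on the donor-adjacent base")
    intron <- e
  }
  irow <- model$introns[model$introns$intron == intron, ]
  ilen <- irow$end - irow$start + 1
  if (abs(offset) > ilen)
    stop("offset ", offset, " exceeds the ", ilen, "-bp length of intron ",
         intron)
  pos <- if (model$strand == "+") {
    if (offset < 0) model$exons$start[e] - abs(offset)
    else model$exons$end[e] + offset
  } else {
    if (offset < 0) model$exons$end[e] + abs(offset)
    else model$exons$start[e] - offset
  }
  list(interval = genomic_interval(model$chrom, pos, pos, model$strand),
       intron = intron, position = pos)
}
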