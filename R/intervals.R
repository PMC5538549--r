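#' Genomic interval
#'
#' A 1-based, fully-closed genomic interval (VCF-style coordinates). This is
#' the internal coordinate convention everywhere in the package; 0-based
#' half-open BED input is converted at the file boundary by
#' [load_gene_model()].
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded).
#' @return an object of class `genomic_interval`.
#' @examples
#' linkage <- genomic_interval("chr21", 33344469, 34196070)
#' interval_length_kb(linkage)  # 852
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  stop_if_not_scalar_number(start, "start")
  stop_if_not_scalar_number(end, "end")
  if (start < 1) stop("interval start must be >= 1")
  if (start > end)
    stop("malformed interval: start (", start, ") > end (", end, ")")
  if (!is.character(strand) || length(strand) != 1L ||
      !strand %in% c("+", "-", "*"))
    stop("strand must be one of '+', '-', '*'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%s-%s (%s), %d bp\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              x$strand, interval_width(x)))
  invisible(x)
}

#' Interval width in base pairs (inclusive)
#' @param iv a [genomic_interval()].
#' @return integer width `end - start + 1`.
#' @export
interval_width <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  as.integer(iv$end - iv$start + 1)
}

#' Interval length in kilobases, rounded to the nearest kb
#'
#' Computed as `round((end - start) / 1000)` with half-up rounding. At kb
#' precision the inclusive-vs-difference (+-1 bp) question is immaterial:
#' both conventions give the same printed value for any interval whose
#' fractional kb is not within 1 bp of .5, which covers all intervals this
#' package reports.
#'
#' @param iv a [genomic_interval()].
#' @return integer length in kb.
#' @examples
#' interval_length_kb(genomic_interval("chr21", 33364965, 34029433))  # 664
#' @export
interval_length_kb <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  as.integer(round_half_up((iv$end - iv$start) / 1000))
}

#' Do two intervals overlap?
#' @param a,b [genomic_interval()] objects.
#' @return logical.
#' @export
interval_overlaps <- function(a, b) {
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  a$chrom == b$chrom && a$start <= b$end && b$start <= a$end
}

#' Intersection of two intervals
#' @param a,b [genomic_interval()] objects on the same chromosome.
#' @return a [genomic_interval()] or `NULL` when the intervals do not overlap.
#' @export
interval_intersect <- function(a, b) {
  if (!interval_overlaps(a, b)) return(NULL)
  genomic_interval(a$chrom, max(a$start, b$start), min(a$end, b$end))
}

#' Does an interval contain a position?
#' @param iv a [genomic_interval()].
#' @param chrom chromosome of the position(s).
#' @param pos numeric vector of positions.
#' @return logical vector.
#' @export
interval_contains <- function(iv, chrom, pos) {
  stopifnot(inherits(iv, "genomic_interval"))
  chrom == iv$chrom & pos >= iv$start & pos <= iv$end
}
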