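#' Detect runs of homozygosity in one individual
#'
#' Scans position-sorted SNP calls for maximal runs of homozygous calls.
#' Heterozygous calls break a run (by default; `het_tolerance` > 0 lets a run
#' greedily absorb that many het calls, which are treated like missing calls
#' for boundary and marker-count purposes). Missing calls never break a run
#' unless more than `max_missing_run` occur consecutively, and never count
#' toward `min_markers`. Segment boundaries are the first and last
#' homozygous marker of the run.
#'
#' @param calls data.frame with columns `marker`, `pos` (sorted ascending)
#'   and `call` in `{"AA","AB","BB","NN"}` (`NN` = missing/low quality).
#' @param individual label attached to the returned segments.
#' @param chrom chromosome name for the returned intervals.
#' @param min_markers minimum homozygous markers supporting a segment
#'   (default 25, usual array-ROH practice).
#' @param min_length_kb minimum segment length in kb (default 500).
#' @param max_missing_run maximum consecutive missing calls skipped within a
#'   run (default 5).
#' @param het_tolerance heterozygous calls absorbed per run (default 0).
#' @return list of `roh_segment` objects: each has `individual`, `interval`,
#'   `n_markers`, and `markers` (data.frame `marker`, `pos`, `allele`).
#' @export
detect_roh <- function(calls, individual = "ind", chrom = "chr21",
                       min_markers = 25, min_length_kb = 500,
                       max_missing_run = 5, het_tolerance = 0) {
  stopifnot(is.data.frame(calls),
            all(c("marker", "pos", "call") %in% names(calls)))
  if (is.unsorted(calls$pos, strictly = FALSE))
    stop("markers must be sorted by position")
  if (!all(calls$call %in% c("AA", "AB", "BB", "NN")))
    stop("calls must be in {AA, AB, BB, NN}")

  segs <- list()
  run_idx <- integer(0)      # indices of homozygous markers in current run
  miss <- 0L                 # pending consecutive missing
  het_used <- 0L
  close_run <- function() {
    if (length(run_idx)) {
      hom <- calls[run_idx, , drop = FALSE]
      segs[[length(segs) + 1L]] <<- list(
        first = hom$pos[1], last = hom$pos[nrow(hom)],
        n = nrow(hom),
        markers = data.frame(marker = hom$marker, pos = hom$pos,
                             allele = substr(hom$call, 1, 1),
                             stringsAsFactors = FALSE))
    }
    run_idx <<- integer(0); miss <<- 0L; het_used <<- 0L
  }
  for (i in seq_len(nrow(calls))) {
    cl <- calls$call[i]
    if (cl %in% c("AA", "BB")) {
      if (miss > max_missing_run) close_run()
      run_idx <- c(run_idx, i)
      miss <- 0L
    } else if (cl == "NN") {
      miss <- miss + 1L
    } else {                                  # heterozygous
      if (length(run_idx) && het_used < het_tolerance &&
          miss <= max_missing_run) {
        het_used <- het_used + 1L
      } else {
        close_run()
      }
    }
  }
  close_run()

  keep <- Filter(function(s) {
    s$n >= min_markers && (s$last - s$first) / 1000 >= min_length_kb
  }, segs)
  lapply(keep, function(s) {
    structure(list(individual = individual,
                   interval = genomic_interval(chrom, s$first, s$last),
                   n_markers = s$n, markers = s$markers),
              class = "roh_segment")
  })
}

#' @export
print.roh_segment <- function(x, ...) {
  cat(sprintf("<roh_segment> %s %s:%s-%s, %d homozygous markers\n",
              x$individual, x$interval$chrom,
              format(x$interval$start, big.mark = ","),
              format(x$interval$end, big.mark = ","), x$n_markers))
  invisible(x)
}

#' Minimal overlapping region of homozygosity across affected individuals
#'
#' Intersects, across affecteds, the ROH segment of each individual that
#' overlaps an anchor interval (e.g. the linkage peak), yielding the minimal
#' shared candidate interval. Markers at which two affecteds are homozygous
#' for *different* alleles inside the candidate are flagged as
#' haplotype-inconsistent.
#'
#' @param segments named list: one element per affected individual, each a
#'   list of `roh_segment` as returned by [detect_roh()].
#' @param anchor a [genomic_interval()] every affected's segment must overlap.
#' @return list with `interval` (the candidate [genomic_interval()]),
#'   `inconsistent_markers` (character vector of marker ids), and
#'   `segments_used` (one `roh_segment` per individual).
#' @export
minimal_overlap_roh <- function(segments, anchor) {
  stopifnot(is.list(segments), length(segments) >= 1L,
            inherits(anchor, "genomic_interval"))
  if (is.null(names(segments)))
    names(segments) <- paste0("affected", seq_along(segments))
  used <- list()
  missing_ids <- character(0)
  for (id in names(segments)) {
    ov <- Filter(function(s) interval_overlaps(s$interval, anchor),
                 segments[[id]])
    if (!length(ov)) {
      missing_ids <- c(missing_ids, id)
      next
    }
    widths <- vapply(ov, function(s)
      interval_width(interval_intersect(s$interval, anchor)), numeric(1))
    used[[id]] <- ov[[which.max(widths)]]
  }
  if (length(missing_ids))
    stop("no ROH segment overlapping the anchor for: ",
         paste(missing_ids, collapse = ", "))
  iv <- used[[1]]$interval
  for (s in used[-1]) {
    iv <- interval_intersect(iv, s$interval)
    if (is.null(iv))
      stop("affected ROH segments have an empty intersection")
  }
  ## haplotype consistency inside the candidate interval
  mk <- do.call(rbind, lapply(used, function(s) {
    d <- s$markers[s$markers$pos >= iv$start & s$markers$pos <= iv$end, ,
                   drop = FALSE]
    if (nrow(d)) cbind(d, individual = s$individual) else NULL
  }))
  inconsistent <- character(0)
  if (!is.null(mk) && nrow(mk)) {
    n_alleles <- tapply(mk$allele, mk$marker, function(a) length(unique(a)))
    inconsistent <- names(n_alleles)[n_alleles > 1]
  }
  list(interval = iv, inconsistent_markers = inconsistent,
       segments_used = used)
}

#' Simplified recessive homozygosity LOD score per marker
#'
#' A singlepoint Lander-Botstein-style homozygosity-mapping statistic, *not*
#' a multipoint pedigree likelihood: for each marker, the log10 ratio of the
#' probability of the affecteds' genotypes under autozygosity versus random
#' mating. With genotyping error rate `eps` and allele-A frequency `q`:
#' `P(hom_A | autozygous) = (1 - eps) * q`, `P(het | autozygous) = eps`,
#' `P(hom_A | random) = q^2`, `P(het | random) = 2 q (1 - q)`. Missing calls
#' contribute 0. Recombination is not modelled.
#'
#' @param genotypes character matrix (individuals x markers) of calls in
#'   `{"AA","AB","BB","NN"}` for the affected individuals.
#' @param q numeric vector of allele-A frequencies per marker, strictly in
#'   (0, 1).
#' @param error_rate genotyping error rate `eps`, strictly in (0, 0.5).
#' @return an object of class `lod_result`: list with `lod` (per-marker
#'   numeric vector) and `contributions` (individuals x markers matrix whose
#'   column sums equal `lod`).
#' @export
homozygosity_lod <- function(genotypes, q, error_rate = 0.005) {
  if (is.vector(genotypes)) genotypes <- matrix(genotypes, nrow = 1)
  stopifnot(is.matrix(genotypes))
  m <- ncol(genotypes)
  q <- rep_len(as.numeric(q), m)
  if (any(q <= 0 | q >= 1)) stop("allele frequency q must be strictly in (0, 1)")
  eps <- error_rate
  stop_if_not_scalar_number(eps, "error_rate")
  if (eps <= 0 || eps >= 0.5) stop("error_rate must be strictly in (0, 0.5)")
  qm <- matrix(q, nrow = nrow(genotypes), ncol = m, byrow = TRUE)
  contrib <- matrix(0, nrow = nrow(genotypes), ncol = m,
                    dimnames = dimnames(genotypes))
  is_aa <- genotypes == "AA"; is_bb <- genotypes == "BB"
  is_ab <- genotypes == "AB"
  contrib[is_aa] <- log10((1 - eps) / qm[is_aa])
  contrib[is_bb] <- log10((1 - eps) / (1 - qm[is_bb]))
  contrib[is_ab] <- log10(eps / (2 * qm[is_ab] * (1 - qm[is_ab])))
  structure(list(lod = colSums(contrib), contributions = contrib),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> %d markers, max LOD %.3f at marker %d\n",
              length(x$lod), max(x$lod), which.max(x$lod)))
  invisible(x)
}
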