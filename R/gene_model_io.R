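#' Load a gene model from BED12 or GFF-lite TSV
#'
#' BED12 is read with its native 0-based half-open coordinates and converted
#' to the internal 1-based inclusive convention; `thickStart`/`thickEnd`
#' define the CDS. The GFF-lite dialect is a 6-column TSV with a header:
#' `seqid`, `feature` (`exon` or `CDS`), `start`, `end`, `strand`,
#' `transcript_id`, 1-based inclusive.
#'
#' @param path file path.
#' @param format `"bed12"` or `"gff"`.
#' @param transcript for GFF-lite files holding several transcripts, which
#'   one to load; defaults to the only transcript present (error if the file
#'   is ambiguous).
#' @return a [gene_model()].
#' @export
load_gene_model <- function(path, format = c("bed12", "gff"),
                            transcript = NULL) {
  format <- match.arg(format)
  if (format == "bed12") load_bed12(path) else load_gff_lite(path, transcript)
}

load_bed12 <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (ncol(d) != 12L) stop("malformed BED12: expected 12 columns, got ", ncol(d))
  if (nrow(d) != 1L) stop("expected one transcript per BED12 file")
  chrom <- d[[1]]; chrom_start <- as.numeric(d[[2]])
  name <- d[[4]]; strand <- d[[6]]
  thick_start <- as.numeric(d[[7]]); thick_end <- as.numeric(d[[8]])
  n_blocks <- as.integer(d[[10]])
  sizes <- as.numeric(strsplit(sub(",$", "", d[[11]]), ",")[[1]])
  starts <- as.numeric(strsplit(sub(",$", "", d[[12]]), ",")[[1]])
  if (length(sizes) != n_blocks || length(starts) != n_blocks)
    stop("malformed BED12: blockCount does not match block lists")
  if (is.unsorted(starts, strictly = TRUE))
    stop("malformed BED12: blockStarts not sorted")
  ex_start <- chrom_start + starts + 1     # to 1-based inclusive
  ex_end <- chrom_start + starts + sizes
  if (any(ex_start[-1] <= ex_end[-n_blocks])) stop("overlapping BED12 blocks")
  exons <- data.frame(start = ex_start, end = ex_end)
  if (strand == "-") exons <- exons[rev(seq_len(n_blocks)), , drop = FALSE]
  rownames(exons) <- NULL
  if (thick_end <= thick_start) stop("BED12 record has no CDS (thickStart == thickEnd)")
  cds_lo <- thick_start + 1; cds_hi <- thick_end
  if (strand == "+")
    gene_model(name, chrom, strand, exons, cds_lo, cds_hi)
  else
    gene_model(name, chrom, strand, exons, cds_hi, cds_lo)
}

load_gff_lite <- function(path, transcript = NULL) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("seqid", "feature", "start", "end", "strand", "transcript_id")
  if (!all(need %in% names(d)))
    stop("malformed GFF-lite: need columns ", paste(need, collapse = ", "))
  ids <- unique(d$transcript_id)
  if (is.null(transcript)) {
    if (length(ids) != 1L)
      stop("GFF-lite file holds ", length(ids),
           " transcripts; pass 'transcript'")
    transcript <- ids
  }
  d <- d[d$transcript_id == transcript, , drop = FALSE]
  if (!nrow(d)) stop("transcript '", transcript, "' not found")
  ex <- d[d$feature == "exon", , drop = FALSE]
  cds <- d[d$feature == "CDS", , drop = FALSE]
  if (!nrow(ex)) stop("no exon rows for transcript '", transcript, "'")
  if (!nrow(cds)) stop("no CDS rows for transcript '", transcript, "'")
  strand <- unique(ex$strand)
  if (length(strand) != 1L) stop("inconsistent strand in GFF-lite records")
  ord <- order(ex$start, decreasing = (strand == "-"))
  exons <- data.frame(start = as.numeric(ex$start[ord]),
                      end = as.numeric(ex$end[ord]))
  cds_lo <- min(as.numeric(cds$start)); cds_hi <- max(as.numeric(cds$end))
  if (strand == "+")
    gene_model(transcript, unique(ex$seqid)[1], strand, exons, cds_lo, cds_hi)
  else
    gene_model(transcript, unique(ex$seqid)[1], strand, exons, cds_hi, cds_lo)
}

#' Write a gene model as a single BED12 line
#' @param model a [gene_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_model_bed12 <- function(model, path) {
  ex <- model$exons[order(model$exons$start), , drop = FALSE]
  chrom_start <- min(ex$start) - 1
  cds_lo <- min(model$cds_start, model$cds_end)
  cds_hi <- max(model$cds_start, model$cds_end)
  line <- paste(model$chrom, format(chrom_start, scientific = FALSE),
                format(max(ex$end), scientific = FALSE),
                model$transcript_id, 0, model$strand,
                format(cds_lo - 1, scientific = FALSE),
                format(cds_hi, scientific = FALSE), 0, nrow(ex),
                paste0(paste(ex$end - ex$start + 1, collapse = ","), ","),
                paste0(paste(ex$start - 1 - chrom_start, collapse = ","), ","),
                sep = "\t")
  writeLines(line, path)
  invisible(path)
}

#' Write one or more gene models as a GFF-lite TSV
#' @param models a [gene_model()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gff <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  rows <- do.call(rbind, lapply(models, function(m) {
    rbind(data.frame(seqid = m$chrom, feature = "exon",
                     start = m$exons$start, end = m$exons$end,
                     strand = m$strand, transcript_id = m$transcript_id),
          data.frame(seqid = m$chrom, feature = "CDS",
                     start = min(m$cds_start, m$cds_end),
                     end = max(m$cds_start, m$cds_end),
                     strand = m$strand, transcript_id = m$transcript_id))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' JSON serialization of a gene model
#' @param model a [gene_model()].
#' @return a JSON string.
#' @export
gene_model_json <- function(model) {
  jsonlite::toJSON(list(
    transcript_id = model$transcript_id, chrom = model$chrom,
    strand = model$strand, exons = model$exons,
    cds_start = model$cds_start, cds_end = model$cds_end),
    auto_unbox = TRUE, digits = NA)
}

#' Rebuild a gene model from its JSON serialization
#' @param json a JSON string or path produced by [gene_model_json()].
#' @return a [gene_model()].
#' @export
gene_model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  gene_model(x$transcript_id, x$chrom, x$strand,
             as.data.frame(x$exons), x$cds_start, x$cds_end)
}
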