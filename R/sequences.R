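#' Genomic sequence segment
#'
#' A plus-strand sequence anchored at a genomic offset. A "genome" in this
#' package is simply a list of such segments, enough to cover the gene loci
#' under study without carrying a whole-chromosome FASTA.
#'
#' @param chrom chromosome name.
#' @param start genomic position of the first base of `seq`.
#' @param seq plus-strand sequence (character scalar, ACGT).
#' @return an object of class `seq_segment`.
#' @export
seq_segment <- function(chrom, start, seq) {
  stopifnot(is.character(chrom), length(chrom) == 1L,
            is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  stop_if_not_scalar_number(start, "start")
  structure(list(chrom = chrom, start = as.numeric(start), seq = seq),
            class = "seq_segment")
}

#' Fetch plus-strand sequence from a genome (list of segments)
#' @param genome a list of [seq_segment()] objects.
#' @param chrom,start,end the 1-based inclusive region to fetch.
#' @return character scalar of plus-strand sequence.
#' @export
genome_fetch <- function(genome, chrom, start, end) {
  if (inherits(genome, "seq_segment")) genome <- list(genome)
  for (s in genome) {
    s_end <- s$start + nchar(s$seq) - 1
    if (s$chrom == chrom && start >= s$start && end <= s_end)
      return(substr(s$seq, start - s$start + 1, end - s$start + 1))
  }
  stop("no sequence segment covers ", chrom, ":", start, "-", end)
}

#' Reverse-complement a DNA string
#' @param x character scalar.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complement_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Translate a DNA string (standard code), trimming to whole codons
#' @param x character scalar of coding sequence.
#' @return character scalar of amino acids (`*` = stop).
#' @export
translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(x, 1, n)),
                                     no.init.codon = TRUE))
}

#' Spliced (mature) transcript sequence of a gene model
#' @param model a [gene_model()].
#' @param genome list of [seq_segment()] covering the gene.
#' @return character scalar, transcript-strand 5'->3'.
#' @export
spliced_transcript_seq <- function(model, genome) {
  parts <- vapply(seq_len(nrow(model$exons)), function(k) {
    s <- genome_fetch(genome, model$chrom, model$exons$start[k],
                      model$exons$end[k])
    if (model$strand == "-") revcomp(s) else s
  }, character(1))
  paste(parts, collapse = "")
}

#' Wild-type CDS sequence (start codon through stop codon)
#' @param model a [gene_model()].
#' @param genome list of [seq_segment()].
#' @return character scalar on the transcript strand.
#' @export
cds_seq <- function(model, genome) {
  tx <- spliced_transcript_seq(model, genome)
  t0 <- genomic_to_transcript(model, model$cds_start)
  substr(tx, t0, t0 + cds_length(model) - 1)
}

#' Transcript-strand sequence of one intron
#' @param model a [gene_model()].
#' @param genome list of [seq_segment()].
#' @param intron intron number in transcript order.
#' @return character scalar, donor (GT) end first.
#' @export
intron_seq <- function(model, genome, intron) {
  row <- model$introns[model$introns$intron == intron, ]
  if (!nrow(row)) stop("no intron ", intron, " in model")
  s <- genome_fetch(genome, model$chrom, row$start, row$end)
  if (model$strand == "-") revcomp(s) else s
}

#' Write a genome (list of segments) as FASTA
#'
#' Records are named `chrom:start-end` so the offsets survive a round trip
#' through [read_genome_fasta()].
#'
#' @param genome list of [seq_segment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (inherits(genome, "seq_segment")) genome <- list(genome)
  seqs <- Biostrings::DNAStringSet(vapply(genome, `[[`, character(1), "seq"))
  names(seqs) <- vapply(genome, function(s)
    sprintf("%s:%s-%s", s$chrom, format(s$start, scientific = FALSE),
            format(s$start + nchar(s$seq) - 1, scientific = FALSE)),
    character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a genome written by [write_genome_fasta()]
#' @param path FASTA path with `chrom:start-end` record names.
#' @return list of [seq_segment()].
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    m <- regmatches(names(seqs)[i],
                    regexec("^(\\S+):([0-9]+)-([0-9]+)$", names(seqs)[i]))[[1]]
    if (!length(m)) stop("FASTA record name lacks chrom:start-end: ",
                         names(seqs)[i])
    seq_segment(m[2], as.numeric(m[3]), as.character(seqs[[i]]))
  })
}
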