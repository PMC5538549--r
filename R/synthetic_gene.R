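## Synthetic gene fixtures. These are *constructed* toy loci whose printed
## anchor numbers (junction CDS coordinate, intron length, premature-stop
## offset, protein lengths, variant coordinates) are imposed by design so the
## downstream arithmetic is exercised on realistic values; everything else
## (codon usage, UTRs, other introns) is seeded random sequence.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
}

random_bases <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

random_intron <- function(len) {
  stopifnot(len >= 4)
  paste0("GT", random_bases(len - 4), "AG")
}

#' Synthetic disease-gene fixture
#'
#' Builds a deterministic toy minus-strand gene on chr21 emulating a
#' recessive splicing-disease locus: 8 exons, a 1701-nt CDS (566 amino acids
#' plus stop), and a poorly spliced 109-bp intron 6 sitting between CDS
#' positions 1046 and 1047. The retained intron 6 carries an in-frame
#' premature stop codon after 52 translated intron bases, and an A>G
#' transcript-strand variant 9 bp upstream of the intron 6 acceptor
#' (`c.1047-9`, genomic plus-strand T>C at 33,582,064). Exon 7's acceptor
#' boundary is genomic 33,582,055; intron 6 extends upward from there, as it
#' must for a minus-strand gene.
#'
#' @param seed integer seed for the random (unconstrained) parts of the
#'   sequence; the structural anchors above are seed-independent.
#' @return an object of class `gene_fixture`: list with `model`
#'   ([gene_model()]), `genome` (list of [seq_segment()]), and `variant`
#'   (chrom, pos, plus-strand ref/alt, transcript-strand ref/alt, cds_anchor,
#'   offset, intron).
#' @export
synthetic_gene_model <- function(seed = 100L) {
  with_seed(seed, {
    nonstop <- setdiff(all_codons(), STOP_CODONS)
    ## spliced transcript: 100 nt 5'UTR + 1701 nt CDS + 150 nt 3'UTR
    cod <- sample(nonstop, 566, replace = TRUE)
    cod[1] <- "ATG"
    cod[349] <- "GCT"   # junction codon: exon-side dinucleotide GC, so the
                        # retained-intron chimeric codon GC+G is Ala, not stop
    cds <- paste(c(cod, "TAA"), collapse = "")
    utr5 <- random_bases(100)
    utr3 <- random_bases(150)
    tx <- paste0(utr5, cds, utr3)            # 1951 nt

    exon_len <- c(200, 150, 200, 180, 216, 200, 300, 505)
    stopifnot(sum(exon_len) == nchar(tx))
    cum <- cumsum(exon_len)
    exon_seq <- substring(tx, c(1, head(cum, -1) + 1), cum)

    ## intron 6 (109 nt, transcript strand): GT donor; mutant-frame codons
    ## over intron bases 2..52 are non-stop; the first in-frame stop (TAA)
    ## occupies intron bases 53-55; the variant base (wild-type A) is intron
    ## base 101, i.e. 9 bp upstream of the AG acceptor.
    c350 <- sample(grep("^T", nonstop, value = TRUE), 1)
    i6 <- paste0("G", c350, paste(sample(nonstop, 16, replace = TRUE),
                                  collapse = ""),
                 "TAA", random_bases(45), "A", random_bases(6), "AG")
    stopifnot(nchar(i6) == 109)
    intron_len <- c(300, 250, 400, 350, 500, 109, 220)
    intron_seq <- c(vapply(intron_len[1:5], random_intron, character(1)),
                    i6, random_intron(intron_len[7]))

    ## interleave exon/intron transcript-strand sequences into the pre-mRNA
    pre <- character(0)
    for (k in 1:8) {
      pre <- c(pre, exon_seq[k])
      if (k < 8) pre <- c(pre, intron_seq[k])
    }
    pre <- paste(pre, collapse = "")

    gene_end <- 33585110
    gene_start <- gene_end - nchar(pre) + 1   # 33581031
    plus_seq <- revcomp(pre)                  # minus-strand gene

    ## genomic exon coordinates: walk down from gene_end in transcript order
    piece_len <- as.vector(rbind(exon_len, c(intron_len, NA)))
    piece_len <- piece_len[!is.na(piece_len)]
    hi <- gene_end - c(0, cumsum(head(piece_len, -1)))
    lo <- hi - piece_len + 1
    is_exon <- rep(c(TRUE, FALSE), length.out = length(piece_len))
    exons <- data.frame(start = lo[is_exon], end = hi[is_exon])

    ## CDS anchors: c.1 at transcript position 101, c.1701 at 1801
    tmp <- gene_model("tmp", "chr21", "-", exons,
                      cds_start = gene_end - 100, cds_end = lo[is_exon][8])
    model <- gene_model("SYNGENE1", "chr21", "-", exons,
                        cds_start = gene_end - 100,
                        cds_end = transcript_to_genomic(tmp, 100 + 1701))
    genome <- list(seq_segment("chr21", gene_start, plus_seq))

    variant_pos <- 33582064
    ref_plus <- genome_fetch(genome, "chr21", variant_pos, variant_pos)
    stopifnot(ref_plus == "T")
    structure(list(
      model = model, genome = genome,
      variant = list(chrom = "chr21", pos = variant_pos,
                     ref = "T", alt = "C",      # genomic plus strand
                     tx_ref = "A", tx_alt = "G", # transcript strand
                     cds_anchor = 1047L, offset = -9L, intron = 6L)),
      class = "gene_fixture")
  })
}

#' Synthetic bystander gene fixture
#'
#' A small plus-strand three-exon gene outside the disease region of
#' homozygosity, used to host coding variants in the synthetic variant
#' fixture. CDS is 450 nt (149 amino acids plus stop).
#'
#' @param seed integer seed.
#' @return a `gene_fixture` (without a `variant` element).
#' @export
synthetic_bystander_gene <- function(seed = 101L) {
  with_seed(seed, {
    nonstop <- setdiff(all_codons(), STOP_CODONS)
    cds <- paste(c("ATG", sample(nonstop, 148, replace = TRUE), "TAA"),
                 collapse = "")
    utr5 <- random_bases(50)
    utr3 <- random_bases(300)
    tx <- paste0(utr5, cds, utr3)            # 800 nt
    exon_len <- c(200, 200, 400)
    cum <- cumsum(exon_len)
    exon_seq <- substring(tx, c(1, head(cum, -1) + 1), cum)
    intron_seq <- c(random_intron(500), random_intron(500))
    pre <- paste0(exon_seq[1], intron_seq[1], exon_seq[2], intron_seq[2],
                  exon_seq[3])
    gene_start <- 35000001
    exons <- data.frame(
      start = gene_start + c(0, 700, 1400),
      end = gene_start + c(199, 899, 1799))
    model <- gene_model("SYNGENE2", "chr21", "+", exons,
                        cds_start = gene_start + 50,
                        cds_end = gene_start + 1400 + (450 - 350) - 1)
    genome <- list(seq_segment("chr21", gene_start, pre))
    structure(list(model = model, genome = genome, variant = NULL),
              class = "gene_fixture")
  })
}

#' @export
print.gene_fixture <- function(x, ...) {
  print(x$model)
  if (!is.null(x$variant))
    cat(sprintf("  variant: %s:%s %s>%s (c.%d%+d, intron %d)\n",
                x$variant$chrom, x$variant$pos, x$variant$ref, x$variant$alt,
                x$variant$cds_anchor, x$variant$offset, x$variant$intron))
  invisible(x)
}
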