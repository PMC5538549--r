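## Toy gene builders for property tests. Constructed independently of the
## package's own synthetic fixtures: coordinates are assembled by hand here.

TOY_BASES <- c("A", "C", "G", "T")
TOY_STOPS <- c("TAA", "TAG", "TGA")
TOY_NONSTOP <- setdiff(names(CODON_TABLE), TOY_STOPS)

toy_rand_bases <- function(n) paste(sample(TOY_BASES, n, TRUE), collapse = "")

## builds a valid toy gene (model + genome + bookkeeping); utr5/utr3 are
## chosen so the CDS is a whole number of codons starting ATG, ending TAA,
## with no internal in-frame stop
make_toy_gene <- function(seed, n_exons = 4, strand = "+", offset = 10000,
                          exon_lens = NULL, intron_lens = NULL,
                          utr5 = 12, utr3 = 15, cds_codons = NULL) {
  set.seed(seed)
  if (is.null(exon_lens)) exon_lens <- sample(30:90, n_exons, replace = TRUE)
  n_exons <- length(exon_lens)
  cds_len <- sum(exon_lens) - utr5 - utr3
  exon_lens[n_exons] <- exon_lens[n_exons] + (3 - cds_len %% 3) %% 3
  cds_len <- sum(exon_lens) - utr5 - utr3
  stopifnot(cds_len >= 9)
  if (is.null(intron_lens))
    intron_lens <- sample(20:60, n_exons - 1, replace = TRUE)
  if (is.null(cds_codons))
    cds_codons <- c("ATG", sample(TOY_NONSTOP, cds_len / 3 - 2, TRUE), "TAA")
  stopifnot(length(cds_codons) * 3 == cds_len)
  tx <- paste0(toy_rand_bases(utr5), paste(cds_codons, collapse = ""),
               toy_rand_bases(utr3))
  cum <- cumsum(exon_lens)
  exon_seq <- substring(tx, c(1, head(cum, -1) + 1), cum)
  intron_seq <- vapply(intron_lens, function(l)
    paste0("GT", toy_rand_bases(l - 4), "AG"), character(1))
  pre <- exon_seq[1]
  for (k in seq_len(n_exons - 1))
    pre <- paste0(pre, intron_seq[k], exon_seq[k + 1])

  total <- nchar(pre)
  if (strand == "+") {
    plus_seq <- pre
    piece_len <- head(as.vector(rbind(exon_lens, c(intron_lens, 0))), -1)
    starts <- offset + c(0, cumsum(head(piece_len, -1)))
    ends <- starts + piece_len - 1
    is_exon <- rep(c(TRUE, FALSE), length.out = length(piece_len))
    exons <- data.frame(start = starts[is_exon], end = ends[is_exon])
  } else {
    plus_seq <- rohsplice::revcomp(pre)
    piece_len <- head(as.vector(rbind(exon_lens, c(intron_lens, 0))), -1)
    his <- (offset + total - 1) - c(0, cumsum(head(piece_len, -1)))
    los <- his - piece_len + 1
    is_exon <- rep(c(TRUE, FALSE), length.out = length(piece_len))
    exons <- data.frame(start = los[is_exon], end = his[is_exon])
  }
  ## local transcript -> genomic map (independent of package functions)
  tx2g <- function(t) {
    cb <- c(0, cumsum(exon_lens))
    k <- which(cum >= t)[1]
    off <- t - cb[k] - 1
    if (strand == "+") exons$start[k] + off else exons$end[k] - off
  }
  model <- gene_model("TOY", "chrT", strand, exons,
                      cds_start = tx2g(utr5 + 1),
                      cds_end = tx2g(utr5 + cds_len))
  list(model = model,
       genome = list(seq_segment("chrT", offset, plus_seq)),
       tx = tx, utr5 = utr5, utr3 = utr3, cds_len = cds_len,
       exon_lens = exon_lens, intron_lens = intron_lens,
       intron_seq = intron_seq)
}

## genomic positions of intron `j` in transcript order (donor end first)
toy_intron_positions_tx_order <- function(model, j) {
  row <- model$introns[model$introns$intron == j, ]
  if (model$strand == "+") seq(row$start, row$end) else seq(row$end, row$start)
}
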