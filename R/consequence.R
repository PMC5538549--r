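#' Protein-level consequence of retaining one intron
#'
#' Translates the coding sequence with intron `intron` retained, from the
#' annotated start codon, and reports the first in-frame stop. Counting
#' conventions (documented because more than one is defensible):
#' `stop_offset_bp` is the number of retained-intron bases translated into
#' protein before the stop terminates translation (the stop codon itself
#' begins at intron base `stop_offset_bp + 1`); `aberrant_residues` counts
#' residues whose codon's *first* base is intronic, so a boundary-chimeric
#' codon straddling the exon/intron junction is not counted aberrant. With
#' these conventions a junction after CDS base 1046 and a stop after 52
#' intron bases give a mutant protein of (1046 + 52) / 3 = 366 residues with
#' 366 - ceil(1046 / 3) = 17 aberrant ones.
#'
#' @param model a [gene_model()].
#' @param genome list of [seq_segment()] covering the gene.
#' @param intron intron number (must lie within the CDS).
#' @param rule_nt nucleotide threshold for the NMD junction rule
#'   (default 50).
#' @return object of class `retained_intron_consequence`: list with
#'   `intron`, `premature_stop`, `stop_offset_bp`, `mutant_protein_len`,
#'   `wildtype_protein_len`, `aberrant_residues`, `nmd_predicted`,
#'   `stop_tx_end` (last base of the stop codon in mutant transcript
#'   coordinates) and `junctions_tx` (mutant-transcript junction positions).
#' @export
retained_intron_orf <- function(model, genome, intron, rule_nt = 50) {
  stopifnot(inherits(model, "gene_model"), intron %in% model$introns$intron)
  wt_cds <- cds_seq(model, genome)
  ## wild-type translatability sanity checks
  if (substr(wt_cds, 1, 3) != "ATG")
    stop("wild-type CDS does not start with ATG")
  if (nchar(wt_cds) %% 3 != 0)
    stop("wild-type CDS length is not a multiple of 3")
  wt_prot <- translate_dna(wt_cds)
  if (substr(wt_prot, nchar(wt_prot), nchar(wt_prot)) != "*" ||
      grepl("\\*", substr(wt_prot, 1, nchar(wt_prot) - 1)))
    stop("wild-type CDS does not translate to a single open reading frame")
  wildtype_len <- nchar(wt_prot) - 1L

  n_before <- cds_bases_before_intron(model, intron)
  if (n_before <= 0 || n_before >= cds_length(model))
    stop("intron ", intron, " is not inside the CDS")
  iseq <- intron_seq(model, genome, intron)
  ilen <- nchar(iseq)

  ## mutant coding sequence: wild-type CDS with the intron inserted; if no
  ## stop appears before its end, translation runs on into the 3' UTR
  tx <- spliced_transcript_seq(model, genome)
  t0 <- genomic_to_transcript(model, model$cds_start)
  downstream <- substr(tx, t0 + n_before, nchar(tx))
  mut_read <- paste0(substr(wt_cds, 1, n_before), iseq, downstream)
  prot <- translate_dna(mut_read)
  stop_idx <- regexpr("*", prot, fixed = TRUE)

  if (stop_idx < 0) {
    res <- list(intron = intron, premature_stop = FALSE,
                stop_offset_bp = NA_integer_,
                mutant_protein_len = NA_integer_,
                wildtype_protein_len = wildtype_len,
                aberrant_residues = NA_integer_,
                nmd_predicted = FALSE, stop_tx_end = NA_integer_,
                junctions_tx = mutant_junctions_tx(model, intron),
                non_stop = TRUE)
    return(structure(res, class = "retained_intron_consequence"))
  }
  stop_idx <- as.integer(stop_idx)            # codon index of the stop
  mutant_len <- stop_idx - 1L
  stop_start_nt <- (stop_idx - 1L) * 3L + 1L  # mutant CDS coordinate
  stop_end_nt <- stop_idx * 3L
  stop_in_intron <- stop_start_nt > n_before &&
    stop_start_nt <= n_before + ilen
  stop_offset <- if (stop_in_intron) as.integer(stop_start_nt - n_before - 1)
                 else NA_integer_
  aberrant <- mutant_len - as.integer(ceiling(n_before / 3))
  premature <- mutant_len < wildtype_len

  junctions <- mutant_junctions_tx(model, intron)
  stop_tx_end <- (t0 - 1L) + stop_end_nt
  nmd <- premature && nmd_predict(stop_tx_end, junctions, rule_nt)
  structure(list(intron = intron, premature_stop = premature,
                 stop_offset_bp = stop_offset,
                 mutant_protein_len = mutant_len,
                 wildtype_protein_len = wildtype_len,
                 aberrant_residues = aberrant,
                 nmd_predicted = nmd, stop_tx_end = stop_tx_end,
                 junctions_tx = junctions, non_stop = FALSE),
            class = "retained_intron_consequence")
}

## exon-exon junction positions of the transcript with intron i retained, in
## mutant transcript coordinates (position of the last base of the upstream
## exon); retaining intron i removes junction i and shifts later ones
mutant_junctions_tx <- function(model, intron) {
  lens <- exon_lengths(model)
  n <- length(lens)
  if (n < 2) return(numeric(0))
  irow <- model$introns[model$introns$intron == intron, ]
  ilen <- irow$end - irow$start + 1
  j <- cumsum(lens)[-n]
  j[seq_along(j) > intron] <- j[seq_along(j) > intron] + ilen
  j[-intron]
}

#' Nonsense-mediated decay prediction (50-nt junction rule)
#'
#' Predicts NMD iff the premature stop lies strictly more than `rule_nt`
#' nucleotides upstream of the *final* exon-exon junction of the mutant
#' transcript. A stop in a retained final intron (no downstream junction)
#' is not predicted to trigger decay; a stop exactly `rule_nt` upstream is
#' not either (strict inequality).
#'
#' @param stop_pos transcript coordinate of the stop codon (last base).
#' @param junctions_tx transcript coordinates of the exon-exon junctions of
#'   the mutant transcript.
#' @param rule_nt rule threshold in nucleotides (default 50).
#' @return logical.
#' @export
nmd_predict <- function(stop_pos, junctions_tx, rule_nt = 50) {
  if (!length(junctions_tx)) return(FALSE)
  (max(junctions_tx) - stop_pos) > rule_nt
}

#' Spliced and unspliced RT-PCR amplicon lengths
#'
#' Given primers in the two exons flanking an intron, returns the length of
#' the spliced product (distance between the primers' outer ends on the
#' mature transcript) and of the unspliced product
#' (`spliced + intron length`).
#'
#' @param model a [gene_model()].
#' @param intron intron number.
#' @param primer_fwd,primer_rev [genomic_interval()]s of the two primers;
#'   each must lie entirely within one of the two exons flanking `intron`
#'   (in either order).
#' @return list with `spliced`, `unspliced`, `intron_length` (bp).
#' @export
amplicon_lengths <- function(model, intron, primer_fwd, primer_rev) {
  stopifnot(intron %in% model$introns$intron,
            inherits(primer_fwd, "genomic_interval"),
            inherits(primer_rev, "genomic_interval"))
  exon_of_primer <- function(p) {
    e1 <- exon_index_of(model, p$start)
    e2 <- exon_index_of(model, p$end)
    if (is.na(e1) || is.na(e2) || e1 != e2)
      stop("primer ", p$chrom, ":", p$start, "-", p$end,
           " is not contained in a single exon")
    e1
  }
  ex <- sort(c(exon_of_primer(primer_fwd), exon_of_primer(primer_rev)))
  if (length(ex) != 2 || ex[1] != intron || ex[2] != intron + 1)
    stop("primers do not flank intron ", intron,
         " (found exons ", paste(ex, collapse = ", "), ")")
  t_all <- genomic_to_transcript(model, c(primer_fwd$start, primer_fwd$end,
                                          primer_rev$start, primer_rev$end))
  spliced <- max(t_all) - min(t_all) + 1
  irow <- model$introns[model$introns$intron == intron, ]
  ilen <- irow$end - irow$start + 1
  list(spliced = spliced, unspliced = spliced + ilen, intron_length = ilen)
}

#' @export
print.retained_intron_consequence <- function(x, ...) {
  cat(sprintf("<retained_intron_consequence> intron %d\n", x$intron))
  if (isTRUE(x$non_stop)) {
    cat("  no in-frame stop before transcript end (non-stop consequence)\n")
  } else {
    cat(sprintf(
      "  stop after %s bp of the intron; protein %d aa (wild-type %d), %d aberrant\n  NMD predicted: %s\n",
      ifelse(is.na(x$stop_offset_bp), "-", x$stop_offset_bp),
      x$mutant_protein_len, x$wildtype_protein_len, x$aberrant_residues,
      x$nmd_predicted))
  }
  invisible(x)
}
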