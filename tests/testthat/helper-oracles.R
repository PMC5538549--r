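## Independent brute-force oracles. These deliberately avoid the code paths
## they check: translation uses a hand-typed codon table, the exact tests use
## direct enumeration, run detection uses O(n^2) window enumeration.

CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(dna) {
  n <- nchar(dna) %/% 3
  if (n == 0) return("")
  codons <- substring(dna, 3 * seq_len(n) - 2, 3 * seq_len(n))
  paste(unname(CODON_TABLE[codons]), collapse = "")
}

## walk codons from position 1, stop at first stop codon; returns protein
## length (aa before the stop) or NA if no stop before the end
oracle_orf_len <- function(dna) {
  aa <- oracle_translate(dna)
  hit <- regexpr("*", aa, fixed = TRUE)
  if (hit < 0) NA_integer_ else as.integer(hit) - 1L
}

## two-sided Fisher exact p for a 2x2 table, by enumeration of all tables
## with the observed margins (sum of probabilities <= observed probability)
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  pk <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  probs <- vapply(lo:hi, pk, numeric(1))
  pobs <- pk(tab[1, 1])
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

## two-sided exact binomial p vs 0.5 by pmf enumeration (log space, so the
## enumeration also works at n = 10^4 without overflow)
oracle_binom <- function(k, n) {
  pmf <- exp(lchoose(n, 0:n) + n * log(0.5))
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

## Holm step-down adjustment from its definition
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

## O(n^2) enumeration of maximal qualifying homozygous runs
oracle_roh_runs <- function(calls, min_markers, min_length_kb,
                            max_missing_run) {
  n <- nrow(calls)
  valid <- function(i, j) {
    w <- calls$call[i:j]
    if (w[1] == "NN" || w[length(w)] == "NN") return(FALSE)
    if (any(w == "AB")) return(FALSE)
    r <- rle(w)
    !any(r$values == "NN" & r$lengths > max_missing_run)
  }
  all_valid <- list()
  for (i in seq_len(n)) for (j in i:n)
    if (valid(i, j)) all_valid[[length(all_valid) + 1L]] <- c(i, j)
  S <- vapply(all_valid, `[`, numeric(1), 1)
  E <- vapply(all_valid, `[`, numeric(1), 2)
  contained <- vapply(seq_along(all_valid), function(k)
    any(S <= S[k] & E >= E[k] & (S < S[k] | E > E[k])), logical(1))
  wins <- all_valid[!contained]
  keep <- Filter(function(w) {
    hom <- sum(calls$call[w[1]:w[2]] %in% c("AA", "BB"))
    hom >= min_markers &&
      (calls$pos[w[2]] - calls$pos[w[1]]) / 1000 >= min_length_kb
  }, wins)
  lapply(keep, function(w) c(start = calls$pos[w[1]], end = calls$pos[w[2]]))
}

## exact permutation p for the two-sample t statistic (all assignments)
oracle_perm_t <- function(x, y) {
  pool <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pool), n)
  tstat <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  }
  t_obs <- abs(tstat(x, y))
  t_all <- apply(idx, 2, function(i) abs(tstat(pool[i], pool[-i])))
  mean(t_all >= t_obs - 1e-12)
}
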