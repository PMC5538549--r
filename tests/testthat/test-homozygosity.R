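calls_df <- function(calls, spacing = 10000, start = 1e6) {
  data.frame(marker = sprintf("m%03d", seq_along(calls)),
             pos = start + spacing * (seq_along(calls) - 1), call = calls)
}

seg_of <- function(seg) c(seg$interval$start, seg$interval$end)

test_that("homozygous runs continue across an allele switch and break on hets", {
  ## AA,AA,AA,BB,BB is one 5-marker homozygous run (ROH does not care which
  ## allele is homozygous at each marker)
  d <- calls_df(c("AA", "AA", "AA", "BB", "BB"))
  segs <- detect_roh(d, min_markers = 3, min_length_kb = 20)
  expect_length(segs, 1)
  expect_equal(seg_of(segs[[1]]), c(d$pos[1], d$pos[5]))
  expect_equal(segs[[1]]$n_markers, 5)
  ## a het call splits the run into two qualifying segments
  d2 <- calls_df(c("AA", "AA", "AA", "AB", "BB", "BB", "BB"))
  segs2 <- detect_roh(d2, min_markers = 3, min_length_kb = 20)
  expect_length(segs2, 2)
  expect_equal(seg_of(segs2[[1]]), c(d2$pos[1], d2$pos[3]))
  expect_equal(seg_of(segs2[[2]]), c(d2$pos[5], d2$pos[7]))
  ## thresholds drop short runs
  expect_length(detect_roh(d2, min_markers = 4, min_length_kb = 20), 0)
  expect_length(detect_roh(d2, min_markers = 2, min_length_kb = 10), 2)
})

test_that("missing calls are skipped but never bound or support a run", {
  d <- calls_df(c("AA", "NN", "NN", "AA", "AA", "NN", "AA", "AB"))
  segs <- detect_roh(d, min_markers = 4, min_length_kb = 0,
                     max_missing_run = 2)
  expect_length(segs, 1)
  expect_equal(seg_of(segs[[1]]), c(d$pos[1], d$pos[7]))
  expect_equal(segs[[1]]$n_markers, 4)      # NN not counted
  ## more than max_missing_run consecutive misses breaks the run
  segs2 <- detect_roh(d, min_markers = 3, min_length_kb = 0,
                      max_missing_run = 1)
  expect_length(segs2, 1)
  expect_equal(seg_of(segs2[[1]]), c(d$pos[4], d$pos[7]))
  expect_error(detect_roh(d[c(2, 1, 3:8), ], min_markers = 1,
                          min_length_kb = 0), "sorted")
})

test_that("an all-heterozygous individual yields no segments", {
  d <- calls_df(rep("AB", 40))
  expect_length(detect_roh(d, min_markers = 2, min_length_kb = 0), 0)
})

test_that("run detection equals brute-force enumeration on random inputs", {
  set.seed(99)
  for (rep in 1:25) {
    calls <- sample(c("AA", "AB", "BB", "NN"), 60, replace = TRUE,
                    prob = c(0.4, 0.2, 0.3, 0.1))
    d <- calls_df(calls, spacing = sample(5000:15000, 1))
    mm <- sample(2:4, 1); mk <- sample(c(0, 20, 50), 1)
    mr <- sample(0:2, 1)
    got <- detect_roh(d, min_markers = mm, min_length_kb = mk,
                      max_missing_run = mr)
    want <- oracle_roh_runs(d, mm, mk, mr)
    expect_equal(lapply(got, seg_of), lapply(want, unname))
  }
})

test_that("cohort segments contain the truth and match the oracle", {
  co <- gen_genotypes(cohort_spec(seed = 55, marker_count = 300,
                                  n_affected = 3, error_rate = 0,
                                  missing_rate = 0))
  for (i in seq_len(nrow(co$truth))) {
    id <- co$truth$individual[i]
    d <- data.frame(marker = co$markers$id, pos = co$markers$pos,
                    call = co$genotypes[id, ])
    segs <- detect_roh(d, min_markers = 25, min_length_kb = 500)
    hits <- Filter(function(s) s$interval$start <= co$truth$start[i] &&
                     s$interval$end >= co$truth$end[i], segs)
    expect_length(hits, 1)   # truth interval contained in a detected run
    want <- oracle_roh_runs(d, 25, 500, 5)
    expect_equal(lapply(segs, seg_of), lapply(want, unname))
  }
})

test_that("minimal overlap intersects anchor-overlapping segments", {
  mk_seg <- function(a, b, spacing = 100) {
    d <- calls_df(rep("AA", (b - a) / spacing + 1), spacing = spacing,
                  start = a)
    detect_roh(d, min_markers = 2, min_length_kb = 0)[[1]]
  }
  anchor <- genomic_interval("chr21", 1e6 - 1e5, 1e6 + 1e6)
  s1 <- mk_seg(1e6 + 100, 1e6 + 900)
  s2 <- mk_seg(1e6 + 300, 1e6 + 1200)
  ov <- minimal_overlap_roh(list(i1 = list(s1), i2 = list(s2)), anchor)
  expect_equal(c(ov$interval$start, ov$interval$end), c(1e6 + 300, 1e6 + 900))
  ## identical segments intersect to themselves with no inconsistency
  ov3 <- minimal_overlap_roh(list(a = list(s1), b = list(s1), c = list(s1)),
                             anchor)
  expect_equal(c(ov3$interval$start, ov3$interval$end), seg_of(s1))
  expect_length(ov3$inconsistent_markers, 0)
  ## order independence
  ov_rev <- minimal_overlap_roh(list(i2 = list(s2), i1 = list(s1)), anchor)
  expect_equal(ov_rev$interval, ov$interval)
  ## a missing overlap names the individual
  far <- mk_seg(9e6, 9e6 + 800)
  expect_error(minimal_overlap_roh(list(i1 = list(s1), odd = list(far)),
                                   anchor), "odd")
})

test_that("cohort minimal overlap contains the locus within each segment", {
  co <- gen_genotypes(cohort_spec(seed = 77, marker_count = 1500,
                                  error_rate = 0, missing_rate = 0.005))
  aff <- co$samples$id[co$samples$role == "affected"]
  segs <- lapply(stats::setNames(aff, aff), function(id)
    detect_roh(data.frame(marker = co$markers$id, pos = co$markers$pos,
                          call = co$genotypes[id, ]), individual = id))
  anchor <- genomic_interval("chr21", 33344469, 34196070)
  ov <- minimal_overlap_roh(segs, anchor)
  core <- cohort_spec(seed = 1)$segment
  expect_true(ov$interval$start <= core$start)
  expect_true(ov$interval$end >= core$end)
  for (id in aff) {
    s <- ov$segments_used[[id]]$interval
    expect_true(s$start <= ov$interval$start && s$end >= ov$interval$end)
  }
})

test_that("LOD contributions match hand-evaluated closed forms", {
  ## one affected, homozygous for the q = 0.1 allele
  r <- homozygosity_lod(matrix("AA"), q = 0.1, error_rate = 0.01)
  expect_equal(r$lod, log10(0.99 * 0.1 / 0.1^2), tolerance = 1e-12)
  expect_equal(r$lod, log10(9.9), tolerance = 1e-12)
  ## heterozygous affected: negative contribution log10(eps / (2 q (1-q)))
  rh <- homozygosity_lod(matrix("AB"), q = 0.3, error_rate = 0.01)
  expect_equal(rh$lod, log10(0.01 / (2 * 0.3 * 0.7)), tolerance = 1e-12)
  expect_lt(rh$lod, 0)
  ## seven affecteds homozygous at q = 0.5, eps -> 0 limit
  r7 <- homozygosity_lod(matrix(rep("AA", 7), ncol = 1), q = 0.5,
                         error_rate = 1e-6)
  expect_equal(r7$lod, 7 * log10(2), tolerance = 1e-4)
  expect_error(homozygosity_lod(matrix("AA"), q = 1, error_rate = 0.01), "q")
})

test_that("LOD is additive over individuals and decreasing in q", {
  g <- matrix(c("AA", "AA", "BB", "AB"), ncol = 1)
  r_all <- homozygosity_lod(g, 0.4, 0.01)
  parts <- vapply(1:4, function(i)
    homozygosity_lod(g[i, , drop = FALSE], 0.4, 0.01)$lod, numeric(1))
  expect_equal(r_all$lod, sum(parts), tolerance = 1e-12)
  expect_equal(colSums(r_all$contributions), r_all$lod)
  ## strictly decreasing in q for all-homozygous-A data
  qs <- seq(0.05, 0.95, by = 0.05)
  lods <- vapply(qs, function(q)
    homozygosity_lod(matrix(rep("AA", 5), ncol = 1), q, 0.01)$lod, numeric(1))
  expect_true(all(diff(lods) < 0))
})

test_that("the peak LOD marker falls inside the shared autozygous segment", {
  co <- gen_genotypes(cohort_spec(seed = 13, marker_count = 2000,
                                  error_rate = 0.005, missing_rate = 0))
  aff <- co$samples$id[co$samples$role == "affected"]
  lod <- homozygosity_lod(co$genotypes[aff, ], co$markers$q, 0.005)
  peak_pos <- co$markers$pos[which.max(lod$lod)]
  ## the statistic peaks where all affecteds are autozygous: the
  ## intersection of the per-individual truth segments
  expect_gte(peak_pos, max(co$truth$start))
  expect_lte(peak_pos, min(co$truth$end))
})
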