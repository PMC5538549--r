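#' Configuration for the RT-PCR / qPCR quantification simulator
#'
#' Per-genotype means and standard deviations of the true
#' fraction-unspliced default to the study conditions (0.85/0.05 affected,
#' 0.38/0.13 parent, 0.24/0.10 control). Relative expression defaults set
#' heterozygous parents to 56% of wild-type levels (the anchored value);
#' the affected-group default of 35% is a free generator parameter.
#'
#' @param groups data.frame with `group`, `n`, `mean_frac`, `sd_frac`,
#'   `rel_expr` (relative expression vs the reference group).
#' @param area_meanlog,area_sdlog log-normal parameters of the total
#'   fluorescence area per sample.
#' @param reference_group group whose expression defines 1.0.
#' @param dct_base mean target-minus-reference Ct in the reference group.
#' @param dct_sd per-sample SD of delta-Ct.
#' @param ct_ref_mean,ct_ref_sd distribution of the reference-assay Ct.
#' @param seed integer seed (required).
#' @return an object of class `splice_quant_config`.
#' @export
splice_quant_config <- function(
    groups = data.frame(group = c("affected", "parent", "control"),
                        n = 20,
                        mean_frac = c(0.85, 0.38, 0.24),
                        sd_frac = c(0.05, 0.13, 0.10),
                        rel_expr = c(0.35, 0.56, 1.00)),
    area_meanlog = log(1000), area_sdlog = 0.4,
    reference_group = "control", dct_base = 8, dct_sd = 0.25,
    ct_ref_mean = 15, ct_ref_sd = 0.3, seed) {
  stopifnot(all(c("group", "n", "mean_frac", "sd_frac", "rel_expr") %in%
                  names(groups)),
            reference_group %in% groups$group)
  if (any(groups$mean_frac < 0 | groups$mean_frac > 1) ||
      any(groups$sd_frac < 0))
    stop("fraction-unspliced parameters out of range")
  if (any(groups$rel_expr <= 0)) stop("relative expression must be positive")
  if (area_sdlog < 0 || dct_sd < 0 || ct_ref_sd < 0)
    stop("scale parameters must be non-negative")
  structure(list(groups = groups, area_meanlog = area_meanlog,
                 area_sdlog = area_sdlog, reference_group = reference_group,
                 dct_base = dct_base, dct_sd = dct_sd,
                 ct_ref_mean = ct_ref_mean, ct_ref_sd = ct_ref_sd,
                 seed = seed),
            class = "splice_quant_config")
}

#' Simulate RT-PCR fragment areas and qPCR Ct values with truth
#'
#' Per sample, a true fraction-unspliced is drawn from the group's normal
#' distribution (truncated to `[0, 1]`) and split over a log-normal total
#' fluorescence area, so the per-sample area ratio equals the drawn
#' fraction exactly. Target/reference Ct pairs are drawn so the group's
#' expected `2^-ddCt` relative expression equals the configured value.
#'
#' @param cfg a [splice_quant_config()].
#' @return list with `areas` (data.frame `sample_id`, `group`,
#'   `area_unspliced`, `area_spliced`), `ct` (data.frame `sample_id`,
#'   `group`, `ct_target`, `ct_reference`) and `truth` (the configured group
#'   parameters plus drawn per-group mean fractions).
#' @export
gen_splice_quant <- function(cfg) {
  stopifnot(inherits(cfg, "splice_quant_config"))
  with_seed(cfg$seed, {
    areas <- list(); cts <- list()
    for (gi in seq_len(nrow(cfg$groups))) {
      g <- cfg$groups[gi, ]
      frac <- pmin(1, pmax(0, rnorm(g$n, g$mean_frac, g$sd_frac)))
      total <- rlnorm(g$n, cfg$area_meanlog, cfg$area_sdlog)
      ids <- sprintf("%s%02d", substr(g$group, 1, 3), seq_len(g$n))
      areas[[gi]] <- data.frame(
        sample_id = ids, group = g$group,
        area_unspliced = frac * total, area_spliced = (1 - frac) * total)
      dct <- cfg$dct_base - log2(g$rel_expr) + rnorm(g$n, 0, cfg$dct_sd)
      ct_ref <- rnorm(g$n, cfg$ct_ref_mean, cfg$ct_ref_sd)
      cts[[gi]] <- data.frame(sample_id = ids, group = g$group,
                              ct_target = ct_ref + dct, ct_reference = ct_ref)
    }
    areas <- do.call(rbind, areas)
    cts <- do.call(rbind, cts)
    truth <- cfg$groups
    truth$drawn_mean_frac <- vapply(split(
      areas$area_unspliced / (areas$area_unspliced + areas$area_spliced),
      areas$group), mean, numeric(1))[truth$group]
    list(areas = areas, ct = cts, truth = truth)
  })
}

#' Write / read the fragment-area and Ct TSVs
#' @param x data.frame (`areas` or `ct` element of [gen_splice_quant()]).
#' @param path TSV path.
#' @return `path` (writer) or a data.frame (reader).
#' @export
write_quant_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant_tsv
#' @export
read_quant_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
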