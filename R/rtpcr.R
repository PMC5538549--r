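#' Percentage unspliced RT-PCR product
#'
#' `100 * area_unspliced / (area_unspliced + area_spliced)`. This is a
#' *relative* splicing measure for comparing genotypes, not an absolute
#' splicing efficiency: the amplification efficiencies of the spliced and
#' unspliced products differ.
#'
#' @param area_unspliced,area_spliced non-negative fluorescence areas
#'   (vectorized); a sample with both areas zero is an error.
#' @return numeric percentage(s) in `[0, 100]`.
#' @examples
#' percent_unspliced(850, 150)  # 85
#' @export
percent_unspliced <- function(area_unspliced, area_spliced) {
  if (any(area_unspliced < 0) || any(area_spliced < 0))
    stop("fluorescence areas must be non-negative")
  tot <- area_unspliced + area_spliced
  if (any(tot == 0)) stop("sample with both areas zero")
  100 * area_unspliced / tot
}

#' Group summaries and pairwise t-tests of percent-unspliced
#'
#' Per-group mean and sample SD (n-1) of the percent-unspliced measure,
#' with all pairwise two-tailed unpaired t-tests (pooled-variance Student by
#' default, Welch via `var_equal = FALSE`) and Holm step-down adjustment
#' over the pairwise family. Groups with fewer than 2 samples are excluded
#' from testing with a warning.
#'
#' @param records data.frame with `sample_id`, `group`, `area_unspliced`,
#'   `area_spliced`.
#' @param var_equal pooled-variance t-test when `TRUE` (default).
#' @return object of class `splice_quant_summary`: list with `summary`
#'   (data.frame `group`, `n`, `mean`, `sd`) and `comparisons` (data.frame
#'   `group1`, `group2`, `t`, `p`, `p_holm`).
#' @export
group_summary <- function(records, var_equal = TRUE) {
  stopifnot(all(c("group", "area_unspliced", "area_spliced") %in%
                  names(records)))
  records$pct <- percent_unspliced(records$area_unspliced,
                                   records$area_spliced)
  by_group <- split(records$pct, records$group)
  summ <- data.frame(group = names(by_group),
                     n = vapply(by_group, length, integer(1)),
                     mean = vapply(by_group, mean, numeric(1)),
                     sd = vapply(by_group, sd, numeric(1)))
  rownames(summ) <- NULL
  testable <- names(by_group)[summ$n >= 2]
  if (length(testable) < length(by_group))
    warning("groups excluded from testing (n < 2): ",
            paste(setdiff(names(by_group), testable), collapse = ", "))
  comparisons <- NULL
  if (length(testable) >= 2) {
    pairs <- combn(testable, 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      tt <- t.test(by_group[[pairs[1, j]]], by_group[[pairs[2, j]]],
                   var.equal = var_equal)
      data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
                 t = unname(tt$statistic), p = tt$p.value)
    }))
    comparisons$p_holm <- p.adjust(comparisons$p, method = "holm")
  }
  structure(list(summary = summ, comparisons = comparisons),
            class = "splice_quant_summary")
}

#' @export
print.splice_quant_summary <- function(x, ...) {
  cat("<splice_quant_summary>\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$comparisons)) print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample `dCt = ct_target - ct_reference`; per group
#' `ddCt = mean dCt(group) - mean dCt(reference group)`; relative expression
#' `2^-ddCt`. The confidence interval is a two-sample t-interval on the
#' ddCt, exponentiated, hence asymmetric around the estimate.
#'
#' @param records data.frame with `sample_id`, `group`, `ct_target`,
#'   `ct_reference`.
#' @param reference_group group defining relative expression 1.0.
#' @param conf confidence level (default 0.95).
#' @param var_equal pooled-variance t-interval when `TRUE` (default Welch).
#' @return data.frame with `group`, `n`, `dct_mean`, `ddct`, `relative`,
#'   `ci_low`, `ci_high` (CI is `NA` for the reference group, whose relative
#'   expression is exactly 1).
#' @export
ddct_relative <- function(records, reference_group = "control", conf = 0.95,
                          var_equal = FALSE) {
  stopifnot(all(c("group", "ct_target", "ct_reference") %in% names(records)))
  if (any(is.na(records$ct_target) | is.na(records$ct_reference)))
    stop("records with missing Ct values")
  records$dct <- records$ct_target - records$ct_reference
  by_group <- split(records$dct, records$group)
  if (!reference_group %in% names(by_group))
    stop("reference group '", reference_group, "' not present")
  ref <- by_group[[reference_group]]
  out <- do.call(rbind, lapply(names(by_group), function(g) {
    d <- by_group[[g]]
    ddct <- mean(d) - mean(ref)
    lo <- hi <- NA_real_
    if (g != reference_group && length(d) >= 2 && length(ref) >= 2) {
      ## degenerate (noise-free) data has no t interval; CI stays NA
      ci <- tryCatch(
        t.test(d, ref, conf.level = conf, var.equal = var_equal)$conf.int,
        error = function(e) NULL)
      if (!is.null(ci)) { lo <- 2^-ci[2]; hi <- 2^-ci[1] }
    }
    data.frame(group = g, n = length(d), dct_mean = mean(d), ddct = ddct,
               relative = 2^-ddct, ci_low = lo, ci_high = hi)
  }))
  rownames(out) <- NULL
  out
}
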