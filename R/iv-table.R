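# Re-analysis of a published IV-level summary table (one row per instrument
# per exposure-outcome association) without re-running selection: per
# association, IVW odds ratios and summed/median instrument R-squared.

#' MR re-analysis of an IV-level association table
#'
#' Consumes a long-format instrument table with one row per instrument and
#' columns `metabolite`, `cancer`, `variant_id`, `beta_exp`, `se_exp`,
#' `beta_out`, `se_out`, `eaf`, `n_exp` (additional columns pass through),
#' and recomputes, per (metabolite, cancer) association: the IVW odds ratio
#' with CI and p, the number of instruments, and the summed instrument
#' R-squared from the per-variant formula ([compute_r2()]).
#'
#' The IVW point estimate is invariant to the fixed vs
#' multiplicative-random choice; `effects_model` only affects the CI.
#'
#' @param iv_table data.frame or TSV/CSV path.
#' @param effects_model Passed to [ivw()].
#' @return data.frame: `metabolite`, `cancer`, `n_iv`, `or_`, `ci_low`,
#'   `ci_high`, `pvalue`, `r2_sum` (fraction).
#' @export
mr_from_iv_table <- function(iv_table, effects_model = "multiplicative_random") {
  if (is.character(iv_table)) iv_table <- data.table::fread(iv_table, data.table = FALSE)
  need <- c("metabolite", "cancer", "variant_id", "beta_exp", "se_exp",
            "beta_out", "se_out", "eaf", "n_exp")
  missing <- setdiff(need, names(iv_table))
  assert_that(length(missing) == 0, "input error: IV table lacks column(s): %s",
              paste(missing, collapse = ", "))
  key <- interaction(iv_table$metabolite, iv_table$cancer, drop = TRUE)
  rows <- lapply(split(iv_table, key), function(g) {
    fit <- ivw(g, effects_model)
    r2 <- compute_r2(g$beta_exp, g$eaf, g$se_exp, g$n_exp)
    data.frame(metabolite = g$metabolite[1], cancer = g$cancer[1],
               n_iv = nrow(g), or_ = fit$or_, ci_low = fit$ci_low,
               ci_high = fit$ci_high, pvalue = fit$pvalue,
               r2_sum = sum(r2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cancer, out$metabolite), , drop = FALSE]
}

#' Median summed instrument R-squared across associations
#'
#' @param iv_table As in [mr_from_iv_table()].
#' @return Median of per-association summed R-squared, as a percentage.
#' @export
median_instrument_r2 <- function(iv_table) {
  res <- mr_from_iv_table(iv_table)
  100 * stats::median(res$r2_sum)
}
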