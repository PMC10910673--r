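# Study-level orchestration: multiple-testing correction, power, the
# six-criterion confidence ledger, reverse MR and replication concordance.

#' Bonferroni significance flags
#'
#' `flag_i = (p_i * m <= alpha)` where `m` is the number of exposures tested
#' against the outcome; a corrected p landing exactly on `alpha` passes (the
#' boundary is inclusive, to numerical tolerance).
#'
#' @param pvalues Numeric vector of IVW p-values.
#' @param m Number of tests for the outcome (>= 1; may exceed
#'   `length(pvalues)`).
#' @param alpha Family-wise error rate (default 0.05).
#' @return Logical vector.
#' @export
bonferroni_flag <- function(pvalues, m, alpha = 0.05) {
  assert_that(m >= 1, "input error: Bonferroni m must be >= 1")
  pvalues * m <= alpha * (1 + 1e-12)
}

#' Asymptotic power of an IVW analysis with a binary outcome
#'
#' The hypothesized odds ratio per SD of exposure is attenuated to the
#' observed-risk scale at case fraction `k_cases`,
#' `b = k (1-k) (OR - 1) / (1 + k (OR - 1))` (the exact risk difference per
#' unit log-odds increase at baseline risk k), giving the non-centrality
#' `NCP = n * r2_sum * b^2 / (k (1-k))` and two-sided power
#' `Phi(-z_{1-a/2} + sqrt(NCP)) + Phi(-z_{1-a/2} - sqrt(NCP))`. Validated
#' against Monte-Carlo power in the test suite (the cited online tool's
#' internals are not published).
#'
#' @param n Outcome GWAS sample size.
#' @param k_cases Case fraction in (0,1).
#' @param r2_sum Total instrument R-squared in `[0,1)`.
#' @param or_ Hypothesized odds ratio per SD of exposure.
#' @param alpha Type-I error rate (default 0.05).
#' @return Power in `[0,1]`.
#' @export
mr_power_binary <- function(n, k_cases, r2_sum, or_, alpha = 0.05) {
  assert_that(all(k_cases > 0 & k_cases < 1), "mr_power_binary: k_cases must be in (0,1)")
  assert_that(all(r2_sum >= 0 & r2_sum < 1), "mr_power_binary: r2_sum must be in [0,1)")
  b <- k_cases * (1 - k_cases) * (or_ - 1) / (1 + k_cases * (or_ - 1))
  ncp <- n * r2_sum * b^2 / (k_cases * (1 - k_cases))
  zq <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-zq + sqrt(ncp)) + stats::pnorm(-zq - sqrt(ncp))
}

#' Six-criterion confidence ledger
#'
#' A significant exposure-outcome association is `confident` iff all of:
#' \enumerate{
#'   \item IVW p passes the per-outcome Bonferroni correction, and at least
#'     one of the other methods has p < 0.05 (`ivw_bonferroni_pass`,
#'     `secondary_support`);
#'   \item the effect direction is identical across all four methods
#'     (`direction_consistent`);
#'   \item every instrument has F > 10 (`all_f_ge_10`);
#'   \item no significant heterogeneity: Cochran Q p > 0.05
#'     (`no_heterogeneity`);
#'   \item no evidence of horizontal pleiotropy: Egger intercept p > 0.05
#'     AND global outlier-test p > 0.05 (`no_pleiotropy`);
#'   \item no single instrument drives the estimate in leave-one-out
#'     (`loo_stable`).
#' }
#'
#' @param results Named list with `mr_result`s `ivw`, `weighted_median`,
#'   `egger` (see [mr_all_methods()]); a `wald` entry, if present, joins the
#'   direction check.
#' @param presso A `presso_result` from [run_presso()].
#' @param loo Output of [leave_one_out()].
#' @param f_stats Numeric vector of instrument F statistics.
#' @param bonferroni_m Number of exposures tested for this outcome.
#' @param metabolite_id,cancer_id Labels carried into the ledger.
#' @param alpha Significance level (default 0.05).
#' @return A one-row `screening_ledger` data.frame with the six criterion
#'   columns, `confident`, and `failed_criteria` (comma-separated, empty
#'   when confident).
#' @export
build_ledger <- function(results, presso, loo, f_stats, bonferroni_m,
                         metabolite_id = NA_character_,
                         cancer_id = NA_character_, alpha = 0.05) {
  for (nm in c("ivw", "weighted_median", "egger")) {
    assert_that(!is.null(results[[nm]]),
                "incomplete-evidence error: missing method result '%s'", nm)
  }
  assert_that(!is.null(presso$global_p), "incomplete-evidence error: missing global pleiotropy test")
  assert_that(!is.null(loo), "incomplete-evidence error: missing leave-one-out results")

  ivw_pass <- bonferroni_flag(results$ivw$pvalue, bonferroni_m, alpha)
  others <- results[setdiff(names(results), "ivw")]
  secondary <- any(vapply(others, function(r) r$pvalue < alpha, logical(1)))
  betas <- vapply(results, `[[`, numeric(1), "beta")
  direction <- length(unique(sign(betas))) == 1
  all_f <- all(f_stats > 10)
  q_p <- results$ivw$q_p %||% 1
  no_het <- q_p > alpha
  no_pleio <- (results$egger$egger_intercept_p > alpha) && (presso$global_p > alpha)
  loo_ok <- !isTRUE(attr(loo, "dominance_flag"))
  crit <- c(ivw_bonferroni_pass = ivw_pass, secondary_support = secondary,
            direction_consistent = direction, all_f_ge_10 = all_f,
            no_heterogeneity = no_het, no_pleiotropy = no_pleio,
            loo_stable = loo_ok)
  out <- data.frame(metabolite_id = metabolite_id, cancer_id = cancer_id,
                    t(as.data.frame(crit)),
                    confident = all(crit),
                    failed_criteria = paste(names(crit)[!crit], collapse = ","),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("screening_ledger", "data.frame")
  out
}

#' Reverse MR analysis
#'
#' Treats the outcome (e.g. cancer) as the exposure and the original
#' exposure (e.g. metabolite) as the outcome, selecting instruments under
#' the stringent profile (P < 5e-8, pairwise LD r2 < 0.001 within 1000 kb).
#' A reverse-causation flag is raised when the IVW p < 0.05.
#'
#' @param cancer_as_exposure,metabolite_as_outcome Canonical
#'   summary-statistic data.frames.
#' @param panel [ld_panel()] or `NULL`.
#' @param cfg Selection configuration; default the stringent profile.
#' @return `list(status, result, reverse_flag, n_iv, reason)`; `status` is
#'   `"ok"` or `"insufficient_instruments"` (then `result` is `NULL` and
#'   `reason` records why).
#' @export
reverse_mr <- function(cancer_as_exposure, metabolite_as_outcome, panel,
                       cfg = clump_config("stringent")) {
  ivs <- select_instruments(cancer_as_exposure, metabolite_as_outcome, panel, cfg)
  if (nrow(ivs) < cfg$min_ivs) {
    return(list(status = "insufficient_instruments", result = NULL,
                reverse_flag = FALSE, n_iv = nrow(ivs),
                reason = attr(ivs, "reason") %||% "too few instruments"))
  }
  fit <- ivw(ivs)
  list(status = "ok", result = fit, reverse_flag = fit$pvalue < 0.05,
       n_iv = nrow(ivs), reason = NULL)
}

#' Concordance between primary and replication results
#'
#' @param primary,replication Named lists (or equal-length lists) of
#'   `mr_result`s matched by name / position.
#' @return `list(n_eligible, n_direction_consistent, n_p_lt_05)`; the last
#'   counts pairs that are direction-consistent AND reach p < 0.05 in
#'   replication.
#' @export
replication_concordance <- function(primary, replication) {
  if (!is.null(names(primary)) && !is.null(names(replication))) {
    shared <- intersect(names(primary), names(replication))
    primary <- primary[shared]; replication <- replication[shared]
  }
  assert_that(length(primary) == length(replication),
              "replication_concordance: unmatched result sets")
  b1 <- vapply(primary, `[[`, numeric(1), "beta")
  b2 <- vapply(replication, `[[`, numeric(1), "beta")
  p2 <- vapply(replication, `[[`, numeric(1), "pvalue")
  consistent <- sign(b1) == sign(b2)
  list(n_eligible = length(b1),
       n_direction_consistent = sum(consistent),
       n_p_lt_05 = sum(consistent & p2 < 0.05))
}

#' Screen one exposure-outcome pair end to end
#'
#' Runs instrument selection (with one outlier-removal pass), the four
#' estimators, the pleiotropy/outlier framework, leave-one-out, power, the
#' confidence ledger and (optionally) reverse MR.
#'
#' @param exposure,outcome Canonical summary-statistic data.frames.
#' @param panel [ld_panel()] or `NULL`.
#' @param cfg [clump_config()].
#' @param seed Integer seed for every stochastic component.
#' @param bonferroni_m Number of exposures screened against this outcome.
#' @param n_sim Simulation count for the outlier framework (default 5000).
#' @param n_boot Weighted-median bootstrap resamples.
#' @param run_reverse Also run reverse MR (default TRUE).
#' @param metabolite_id,cancer_id Labels.
#' @return `list(status, ivs, results, presso, loo, power, ledger, reverse,
#'   reason)`; `status = "no_instruments"` short-circuits with the recorded
#'   selection `reason`.
#' @export
screen_pair <- function(exposure, outcome, panel, cfg = clump_config(), seed,
                        bonferroni_m = 1, n_sim = 5000, n_boot = 1000,
                        run_reverse = TRUE,
                        metabolite_id = "exposure", cancer_id = "outcome") {
  assert_that(!missing(seed), "screen_pair: seed is required")
  ivs <- select_instruments(exposure, outcome, panel, cfg,
                            presso_n_sim = n_sim, seed = derive_seed(seed, 1))
  if (nrow(ivs) < cfg$min_ivs) {
    return(list(status = "no_instruments", ivs = ivs, results = NULL,
                presso = NULL, loo = NULL, power = NA_real_, ledger = NULL,
                reverse = NULL, reason = attr(ivs, "reason")))
  }
  results <- mr_all_methods(ivs, seed = derive_seed(seed, 2), n_boot = n_boot)
  presso <- if (nrow(ivs) >= 4) {
    run_presso(ivs, n_sim = n_sim, seed = derive_seed(seed, 3))
  } else {
    list(global_p = 1, outlier_ids = character(0), raw = results$ivw)
  }
  loo <- leave_one_out(ivs)
  k_cases <- attr(outcome, "k_cases") %||% 0.5
  pow <- mr_power_binary(stats::median(ivs$n_out, na.rm = TRUE), k_cases,
                         min(sum(ivs$r2_exp), 0.99), results$ivw$or_)
  ledger <- build_ledger(results, presso, loo, ivs$f_stat, bonferroni_m,
                         metabolite_id = metabolite_id, cancer_id = cancer_id)
  reverse <- if (run_reverse) reverse_mr(outcome, exposure, panel) else NULL
  list(status = "ok", ivs = ivs, results = results, presso = presso,
       loo = loo, power = pow, ledger = ledger, reverse = reverse,
       reason = NULL)
}
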