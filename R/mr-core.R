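# Univariable MR estimators and diagnostics.
#
# All estimators consume a harmonized instrument table (beta_exp, se_exp,
# beta_out, se_out) and return an `mr_result`. The causal effect is on the
# log-odds scale per SD of exposure; or_ = exp(beta).

#' @noRd
mr_result <- function(method, n_iv, beta, se, pvalue, ci_q = stats::qnorm(0.975), ...) {
  structure(list(method = method, n_iv = n_iv, beta = beta, se = se,
                 or_ = exp(beta),
                 ci_low = exp(beta - ci_q * se),
                 ci_high = exp(beta + ci_q * se),
                 pvalue = pvalue, ...),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR %s estimate (%d IVs)\n", x$method, x$n_iv))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), beta %.4f (SE %.4f), p = %.3g\n",
              x$or_, x$ci_low, x$ci_high, x$beta, x$se, x$pvalue))
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept %.4f, p = %.3g\n", x$egger_intercept, x$egger_intercept_p))
  }
  if (!is.null(x$q_stat)) {
    cat(sprintf("  Cochran Q %.2f on %d df, p = %.3g\n", x$q_stat, x$q_df, x$q_p))
  }
  invisible(x)
}

#' @noRd
wald_terms <- function(ivs) {
  assert_that(all(ivs$beta_exp != 0), "undefined-ratio error: beta_exp = 0")
  r <- ivs$beta_out / ivs$beta_exp
  se <- ivs$se_out / abs(ivs$beta_exp)
  list(r = r, se = se, w = 1 / se^2)
}

#' Wald ratio for a single instrument
#'
#' `beta = beta_out / beta_exp` with the first-order delta-method standard
#' error `se_out / |beta_exp|` (exposure uncertainty ignored, consistent with
#' the IVW weighting); p-value from the normal approximation.
#'
#' @param iv One-row `harmonized_ivs` data.frame.
#' @return An `mr_result`.
#' @export
wald_ratio <- function(iv) {
  assert_that(nrow(iv) == 1, "wald_ratio expects exactly one instrument")
  t <- wald_terms(iv)
  mr_result("wald", 1L, t$r, t$se, 2 * stats::pnorm(-abs(t$r / t$se)))
}

#' Inverse-variance-weighted estimate
#'
#' Precision-weighted mean of per-instrument Wald ratios
#' (`w_j = 1/se_wald_j^2`), equivalent to a zero-intercept weighted
#' regression of `beta_out` on `beta_exp` with weights `1/se_out^2`. Under
#' `"fixed"` the SE is `(sum w_j)^{-1/2}`; under `"multiplicative_random"`
#' (default) it is inflated by `max(1, sqrt(Q/(n_iv - 1)))` where Q is
#' Cochran's heterogeneity statistic. The point estimate is identical under
#' both.
#'
#' @param ivs `harmonized_ivs` data.frame (>= 1 row).
#' @param effects_model `"multiplicative_random"` or `"fixed"`.
#' @return An `mr_result` carrying `q_stat`, `q_df`, `q_p` when `n_iv >= 2`.
#' @export
ivw <- function(ivs, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  k <- nrow(ivs)
  assert_that(k >= 1, "input error: ivw requires at least one instrument")
  t <- wald_terms(ivs)
  beta <- sum(t$w * t$r) / sum(t$w)
  se_fixed <- sqrt(1 / sum(t$w))
  q <- sum(t$w * (t$r - beta)^2)
  scale <- if (effects_model == "multiplicative_random" && k >= 2) {
    max(1, sqrt(q / (k - 1)))
  } else 1
  se <- se_fixed * scale
  extras <- if (k >= 2) {
    list(q_stat = q, q_df = k - 1L, q_p = stats::pchisq(q, k - 1, lower.tail = FALSE))
  } else list()
  do.call(mr_result, c(list(method = "ivw", n_iv = k, beta = beta, se = se,
                            pvalue = 2 * stats::pnorm(-abs(beta / se)),
                            effects_model = effects_model),
                       extras))
}

#' @noRd
weighted_median_est <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(r[1])
  if (cum[length(cum)] <= 0.5) return(r[length(r)])
  below <- max(which(cum < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

#' Weighted-median estimate
#'
#' Consistent when instruments carrying at least half of the weight are
#' valid. Ratios are ordered and the inverse-variance-normalized weights are
#' accumulated; the estimate interpolates linearly at cumulative weight 0.5.
#' The SE comes from a seeded parametric bootstrap resampling each ratio
#' from `Normal(r_j, se_wald_j)`.
#'
#' @param ivs `harmonized_ivs` data.frame (>= 3 rows).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @return An `mr_result`.
#' @export
weighted_median <- function(ivs, n_boot = 1000, seed) {
  k <- nrow(ivs)
  assert_that(k >= 3, "insufficient-instrument error: weighted_median requires >= 3 IVs")
  assert_that(!missing(seed), "weighted_median: seed is required")
  t <- wald_terms(ivs)
  beta <- weighted_median_est(t$r, t$w)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  draws <- matrix(stats::rnorm(n_boot * k, mean = rep(t$r, each = n_boot),
                               sd = rep(t$se, each = n_boot)), nrow = n_boot)
  boots <- apply(draws, 1, weighted_median_est, w = t$w)
  se <- stats::sd(boots)
  mr_result("weighted_median", k, beta, se, 2 * stats::pnorm(-abs(beta / se)),
            n_boot = n_boot, seed = as.integer(seed))
}

#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Egger regression
#'
#' Weighted least squares of `beta_out` on `beta_exp` with a free intercept
#' and weights `1/se_out^2`; instruments must be oriented `beta_exp >= 0`
#' (the [harmonize()] convention). The slope is the pleiotropy-adjusted
#' causal effect; the intercept estimates average directional pleiotropy.
#' Standard errors are inflated by `max(1, sqrt(Q_egger/(n_iv - 2)))`;
#' p-values and the CI use the t distribution on `n_iv - 2` df.
#'
#' @param ivs `harmonized_ivs` data.frame (>= 3 rows).
#' @return An `mr_result` with `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`, `q_stat`, `q_df`, `q_p`.
#' @export
egger <- function(ivs) {
  k <- nrow(ivs)
  assert_that(k >= 3, "insufficient-instrument error: egger requires >= 3 IVs")
  x <- abs(ivs$beta_exp)  # orientation guard; harmonized IVs already >= 0
  y <- ivs$beta_out * sign(ivs$beta_exp)
  assert_that(stats::var(x) > 0, "collinearity error: all beta_exp identical")
  w <- 1 / ivs$se_out^2
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  # lm SEs already carry sigma; floor the dispersion at 1 (multiplicative
  # random-effects convention)
  infl <- 1 / min(1, sm$sigma)
  b <- co["x", "Estimate"]; b_se <- co["x", "Std. Error"] * infl
  a <- co["(Intercept)", "Estimate"]; a_se <- co["(Intercept)", "Std. Error"] * infl
  df <- k - 2
  q <- sum(w * stats::residuals(fit)^2)
  mr_result("egger", k, b, b_se,
            pvalue = 2 * stats::pt(-abs(b / b_se), df),
            ci_q = stats::qt(0.975, df),
            egger_intercept = a, egger_intercept_se = a_se,
            egger_intercept_p = 2 * stats::pt(-abs(a / a_se), df),
            q_stat = q, q_df = as.integer(df),
            q_p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (r_j - beta_ref)^2` over Wald ratios with inverse-variance
#' weights; upper-tail chi-square p on `n_iv - 1` df.
#'
#' @param ivs `harmonized_ivs` data.frame (>= 2 rows).
#' @param beta_ref Reference causal estimate; defaults to the IVW estimate.
#' @return `list(q_stat, df, p)`.
#' @export
cochran_q <- function(ivs, beta_ref = NULL) {
  k <- nrow(ivs)
  assert_that(k >= 2, "cochran_q requires >= 2 instruments")
  t <- wald_terms(ivs)
  if (is.null(beta_ref)) beta_ref <- sum(t$w * t$r) / sum(t$w)
  q <- sum(t$w * (t$r - beta_ref)^2)
  list(q_stat = q, df = k - 1L, p = stats::pchisq(q, k - 1, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates IVW excluding each instrument in turn. A dominance flag is
#' raised when any exclusion flips the sign of the causal estimate, or moves
#' the 95% CI across OR = 1 in either direction relative to the full fit.
#'
#' @param ivs `harmonized_ivs` data.frame (>= 3 rows).
#' @param effects_model Passed to [ivw()].
#' @return data.frame (one row per excluded instrument: `excluded_id`,
#'   `beta`, `se`, `or_`, `ci_low`, `ci_high`, `pvalue`) with attribute
#'   `dominance_flag`.
#' @export
leave_one_out <- function(ivs, effects_model = "multiplicative_random") {
  k <- nrow(ivs)
  assert_that(k >= 3, "leave_one_out requires >= 3 instruments")
  full <- ivw(ivs, effects_model)
  rows <- lapply(seq_len(k), function(j) {
    fit <- ivw(ivs[-j, , drop = FALSE], effects_model)
    data.frame(excluded_id = ivs$variant_id[j], beta = fit$beta, se = fit$se,
               or_ = fit$or_, ci_low = fit$ci_low, ci_high = fit$ci_high,
               pvalue = fit$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  full_excl1 <- full$ci_low > 1 || full$ci_high < 1
  loo_excl1 <- out$ci_low > 1 | out$ci_high < 1
  flag <- any(sign(out$beta) != sign(full$beta)) || any(loo_excl1 != full_excl1)
  attr(out, "dominance_flag") <- flag
  attr(out, "full_beta") <- full$beta
  out
}

#' Run all four univariable estimators
#'
#' Convenience wrapper returning IVW (primary), weighted median, Egger and,
#' when only one instrument is available, the Wald ratio.
#'
#' @param ivs `harmonized_ivs` data.frame.
#' @param seed Seed for the weighted-median bootstrap.
#' @param n_boot Bootstrap resamples for the weighted median.
#' @param effects_model IVW effects model.
#' @return Named list of `mr_result`s (`ivw`, `weighted_median`, `egger`).
#' @export
mr_all_methods <- function(ivs, seed, n_boot = 1000,
                           effects_model = "multiplicative_random") {
  assert_that(nrow(ivs) >= 3, "mr_all_methods requires >= 3 instruments")
  list(ivw = ivw(ivs, effects_model),
       weighted_median = weighted_median(ivs, n_boot = n_boot, seed = seed),
       egger = egger(ivs))
}

#' Serialize MR results to a flat table
#'
#' One row per method, mirroring the usual reporting layout (method, number
#' of IVs, OR with CI, p, heterogeneity and intercept diagnostics).
#' @param results List of `mr_result`s.
#' @export
mr_results_table <- function(results) {
  do.call(rbind, lapply(results, function(x) {
    data.frame(method = x$method, n_iv = x$n_iv, beta = x$beta, se = x$se,
               or_ = x$or_, ci_low = x$ci_low, ci_high = x$ci_high,
               pvalue = x$pvalue,
               egger_intercept = x$egger_intercept %||% NA_real_,
               egger_intercept_p = x$egger_intercept_p %||% NA_real_,
               q_stat = x$q_stat %||% NA_real_,
               q_p = x$q_p %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
}
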