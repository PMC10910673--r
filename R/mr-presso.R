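# Simulation-based residual-sum-of-squares pleiotropy framework:
# global test, per-instrument outlier test, distortion test.
#
# Leave-one-out fitted values use the zero-intercept weighted regression
# convention of ivw(effects_model = "fixed"): beta_hat = sum(w x y)/sum(w x^2)
# with w = 1/se_out^2. All simulation draws are seeded and the add-one
# p-value estimator is used throughout, so p can never be exactly zero.

# Leave-one-out fitted outcome effect for every instrument, vectorized over
# rows of (X, Y) matrices (one row per simulated replicate).
#' @noRd
loo_fitted <- function(X, Y, w) {
  A <- sweep(X * Y, 2, w, `*`)   # w_j x_j y_j
  B <- sweep(X * X, 2, w, `*`)   # w_j x_j^2
  num <- rowSums(A) - A
  den <- rowSums(B) - B
  (num / den) * X                # fitted_j = beta_{-j} * x_j
}

#' @noRd
presso_sim <- function(ivs, n_sim, seed) {
  k <- nrow(ivs)
  assert_that(k >= 4, "insufficient-instrument error: the outlier framework requires >= 4 IVs")
  assert_that(n_sim >= 1000, "presso: n_sim must be >= 1000")
  assert_that(!missing(seed) && !is.null(seed), "presso: seed is required")
  x <- ivs$beta_exp; y <- ivs$beta_out
  w <- 1 / ivs$se_out^2
  X <- matrix(x, nrow = 1); Y <- matrix(y, nrow = 1)
  fitted_obs <- loo_fitted(X, Y, w)[1, ]
  resid2_obs <- w * (y - fitted_obs)^2
  rss_obs <- sum(resid2_obs)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  Xs <- matrix(stats::rnorm(n_sim * k, mean = rep(x, each = n_sim),
                            sd = rep(ivs$se_exp, each = n_sim)), nrow = n_sim)
  Ys <- matrix(stats::rnorm(n_sim * k, mean = rep(fitted_obs, each = n_sim),
                            sd = rep(ivs$se_out, each = n_sim)), nrow = n_sim)
  fitted_sim <- loo_fitted(Xs, Ys, w)
  resid2_sim <- sweep((Ys - fitted_sim)^2, 2, w, `*`)  # n_sim x k
  list(k = k, rss_obs = rss_obs, resid2_obs = resid2_obs,
       rss_sim = rowSums(resid2_sim), resid2_sim = resid2_sim)
}

#' Global pleiotropy test
#'
#' For each instrument the residual is taken against the fixed-effect IVW
#' fit that excludes it; the observed weighted residual sum of squares is
#' compared with a simulated null in which `beta_exp* ~ N(beta_exp, se_exp)`
#' and `beta_out* ~ N(fitted, se_out)`. The p-value uses the add-one
#' estimator `(1 + #{RSS* >= RSS_obs}) / (n_sim + 1)`.
#'
#' @param ivs `harmonized_ivs` data.frame (>= 4 rows).
#' @param n_sim Number of simulated replicates (>= 1000; default 5000).
#' @param seed Integer seed (required).
#' @return `list(rss_obs, global_p, per_iv_obs)` where `per_iv_obs` is the
#'   observed weighted squared residual per instrument.
#' @export
presso_global <- function(ivs, n_sim = 5000, seed) {
  s <- presso_sim(ivs, n_sim, seed)
  global_p <- (1 + sum(s$rss_sim >= s$rss_obs)) / (n_sim + 1)
  list(rss_obs = s$rss_obs, global_p = global_p, per_iv_obs = s$resid2_obs)
}

#' Per-instrument outlier test
#'
#' The per-instrument p-value is the (add-one) proportion of simulated
#' squared residuals for that instrument exceeding the observed one,
#' Bonferroni-multiplied by the number of instruments and capped at 1.
#' Instruments with corrected p < 0.05 are outliers.
#'
#' @inheritParams presso_global
#' @return data.frame with `variant_id`, `p_raw`, `p_bonferroni`, one row
#'   per instrument.
#' @export
presso_outlier <- function(ivs, n_sim = 5000, seed) {
  s <- presso_sim(ivs, n_sim, seed)
  exceed <- colSums(s$resid2_sim >= matrix(s$resid2_obs, nrow = nrow(s$resid2_sim),
                                           ncol = s$k, byrow = TRUE))
  p_raw <- (1 + exceed) / (n_sim + 1)
  data.frame(variant_id = ivs$variant_id, p_raw = p_raw,
             p_bonferroni = pmin(1, p_raw * s$k), stringsAsFactors = FALSE)
}

#' Distortion test
#'
#' Measures how much the flagged outliers distort the causal estimate:
#' `coefficient = 100 * (beta_raw - beta_corrected) / |beta_corrected|`.
#' The null distribution recomputes the coefficient over `n_sim` random
#' outlier-index sets of the same size; p is the add-one two-sided tail
#' proportion.
#'
#' @param ivs `harmonized_ivs` data.frame.
#' @param outlier_ids Non-empty character vector of flagged instrument ids.
#' @param n_sim Number of random index sets (default 5000).
#' @param seed Integer seed (required).
#' @return `list(distortion_coef, distortion_p)`.
#' @export
presso_distortion <- function(ivs, outlier_ids, n_sim = 5000, seed) {
  assert_that(length(outlier_ids) > 0, "presso_distortion: outlier_ids must be non-empty")
  k <- nrow(ivs)
  n_out <- sum(ivs$variant_id %in% outlier_ids)
  assert_that(n_out < k, "degenerate-correction error: all instruments flagged as outliers")
  beta_raw <- ivw(ivs, "fixed")$beta
  corrected <- ivs[!ivs$variant_id %in% outlier_ids, , drop = FALSE]
  beta_corr <- ivw(corrected, "fixed")$beta
  coef_obs <- 100 * (beta_raw - beta_corr) / abs(beta_corr)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  coefs <- vapply(seq_len(n_sim), function(i) {
    idx <- sample.int(k, n_out)
    b <- ivw(ivs[-idx, , drop = FALSE], "fixed")$beta
    100 * (beta_raw - b) / abs(b)
  }, numeric(1))
  p <- (1 + sum(abs(coefs) >= abs(coef_obs))) / (n_sim + 1)
  list(distortion_coef = coef_obs, distortion_p = p)
}

#' Full outlier-framework run
#'
#' Global test, outlier test, outlier-corrected IVW and distortion test in
#' one seeded pass. When no outlier is flagged the raw IVW estimate is
#' reported and `corrected` / `distortion_p` stay `NULL`.
#'
#' @inheritParams presso_global
#' @param effects_model Effects model for the reported estimates.
#' @return A `presso_result` list: `rss_obs`, `global_p`, `outlier_ids`,
#'   `raw`, `corrected`, `distortion_coef`, `distortion_p`, `n_sim`, `seed`.
#' @export
run_presso <- function(ivs, n_sim = 5000, seed,
                       effects_model = "multiplicative_random") {
  glob <- presso_global(ivs, n_sim, seed)
  out <- presso_outlier(ivs, n_sim, seed)
  outlier_ids <- out$variant_id[out$p_bonferroni < 0.05]
  res <- list(rss_obs = glob$rss_obs, global_p = glob$global_p,
              outlier_table = out, outlier_ids = outlier_ids,
              raw = ivw(ivs, effects_model),
              corrected = NULL, distortion_coef = NULL, distortion_p = NULL,
              n_sim = as.integer(n_sim), seed = as.integer(seed))
  if (length(outlier_ids) > 0 && length(outlier_ids) < nrow(ivs)) {
    res$corrected <- ivw(ivs[!ivs$variant_id %in% outlier_ids, , drop = FALSE],
                         effects_model)
    dist <- presso_distortion(ivs, outlier_ids, n_sim, seed)
    res$distortion_coef <- dist$distortion_coef
    res$distortion_p <- dist$distortion_p
  }
  structure(res, class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("Pleiotropy residual-sum-of-squares test (n_sim = %d, seed = %d)\n",
              x$n_sim, x$seed))
  cat(sprintf("  RSS = %.3f, global p = %.4g\n", x$rss_obs, x$global_p))
  if (length(x$outlier_ids)) {
    cat(sprintf("  outliers: %s\n", paste(x$outlier_ids, collapse = ", ")))
    cat(sprintf("  corrected OR %.3f, distortion %.1f%% (p = %.3g)\n",
                x$corrected$or_, x$distortion_coef, x$distortion_p))
  } else {
    cat("  no outliers detected; raw estimate stands\n")
  }
  invisible(x)
}
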