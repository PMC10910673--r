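# Approximate-Bayes-factor colocalization over the five single-causal-variant
# hypotheses:
#   H0 no association with either trait; H1/H2 association with one trait
#   only; H3 two distinct causal variants; H4 one shared causal variant.

#' Wakefield log approximate Bayes factor
#'
#' With `z = beta/se`, `V = se^2`, `W = prior_sd^2` and shrinkage
#' `r = W / (V + W)`: `log ABF = 0.5 log(1 - r) + 0.5 r z^2`. Vectorized.
#'
#' @param beta,se Marginal association and its standard error (`se > 0`).
#' @param prior_sd Prior SD of the true effect (> 0); conventional defaults
#'   are 0.15 for a quantitative trait and 0.2 for log-odds of a binary
#'   trait.
#' @return Log ABF (natural log).
#' @export
wakefield_log_abf <- function(beta, se, prior_sd) {
  assert_that(all(se > 0), "wakefield_log_abf: se must be > 0")
  assert_that(all(prior_sd > 0), "wakefield_log_abf: prior_sd must be > 0")
  z <- beta / se
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  0.5 * log(1 - r) + 0.5 * r * z^2
}

#' Colocalization of two traits at one locus
#'
#' Enumerates the single-variant configurations: per-hypothesis evidence is
#' accumulated on the log scale (log-sum-exp) over single variants (H1, H2,
#' H4) and ordered pairs of distinct variants (H3), weighted by the prior
#' probabilities `p1`, `p2`, `p12` of a variant being causal for trait 1
#' only, trait 2 only, or both.
#'
#' @param trait1,trait2 data.frames with `variant_id`, `beta`, `se`
#'   (regional summary statistics); the variant intersection is analysed.
#' @param priors Named numeric vector `c(p1=, p2=, p12=)`; defaults
#'   `1e-4, 1e-4, 1e-5`.
#' @param sd_prior1,sd_prior2 Wakefield prior SDs for the two traits.
#' @param locus_id Label carried into the result.
#' @return A `coloc_result`: `locus_id`, `pp` (named PP0..PP4, summing to
#'   1), `n_variants`, `priors`.
#' @export
coloc_abf <- function(trait1, trait2,
                      priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                      sd_prior1 = 0.15, sd_prior2 = 0.2,
                      locus_id = NA_character_) {
  common <- intersect(trait1$variant_id, trait2$variant_id)
  assert_that(length(common) > 0, "input error: empty variant intersection")
  n_drop <- (nrow(trait1) - length(common)) + (nrow(trait2) - length(common))
  if (n_drop > 0) msg("coloc_abf: %d variant(s) outside the intersection dropped", n_drop)
  t1 <- trait1[match(common, trait1$variant_id), ]
  t2 <- trait2[match(common, trait2$variant_id), ]
  a1 <- wakefield_log_abf(t1$beta, t1$se, sd_prior1)
  a2 <- wakefield_log_abf(t2$beta, t2$se, sd_prior2)

  l1 <- logsumexp(a1)
  l2 <- logsumexp(a2)
  l12 <- logsumexp(a1 + a2)              # shared-variant configurations
  lH0 <- 0
  lH1 <- log(priors[["p1"]]) + l1
  lH2 <- log(priors[["p2"]]) + l2
  # sum over i != j of exp(a1_i + a2_j) = (sum_i)(sum_j) - sum_i(a1_i + a2_i)
  lH3 <- if (length(common) > 1) {
    log(priors[["p1"]]) + log(priors[["p2"]]) + logdiffexp(l1 + l2, l12)
  } else -Inf
  lH4 <- log(priors[["p12"]]) + l12

  lh <- c(PP0 = lH0, PP1 = lH1, PP2 = lH2, PP3 = lH3, PP4 = lH4)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  structure(list(locus_id = locus_id, pp = pp, n_variants = length(common),
                 priors = priors), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization at %s (%d variants)\n",
              x$locus_id %||% "locus", x$n_variants))
  print(round(x$pp, 4))
  invisible(x)
}

#' Colocalization at every instrument locus
#'
#' For each instrument, regional summary statistics within `window_kb`
#' kilobases on the instrument's chromosome are extracted from both traits
#' and colocalized. The association-level summary reports whether any locus
#' reaches `pp4_threshold` and the fraction of loci that do.
#'
#' @param ivs `harmonized_ivs` data.frame (needs `chrom`, `pos`).
#' @param exposure_region_stats,outcome_region_stats Regional summary
#'   statistics (`variant_id`, `chrom`, `pos`, `beta`, `se`).
#' @param window_kb Half-window around each instrument (default 500).
#' @param pp4_threshold Shared-causal-variant posterior treated as evidence
#'   of colocalization (default 0.5, "moderate").
#' @param ... Passed to [coloc_abf()] (priors, prior SDs).
#' @return `list(results = list of coloc_result, summary = list(any_coloc,
#'   fraction, n_loci))`.
#' @export
coloc_at_ivs <- function(ivs, exposure_region_stats, outcome_region_stats,
                         window_kb = 500, pp4_threshold = 0.5, ...) {
  window_bp <- window_kb * 1000
  results <- lapply(seq_len(nrow(ivs)), function(i) {
    sel1 <- exposure_region_stats$chrom == ivs$chrom[i] &
      abs(exposure_region_stats$pos - ivs$pos[i]) <= window_bp
    sel2 <- outcome_region_stats$chrom == ivs$chrom[i] &
      abs(outcome_region_stats$pos - ivs$pos[i]) <= window_bp
    coloc_abf(exposure_region_stats[sel1, , drop = FALSE],
              outcome_region_stats[sel2, , drop = FALSE],
              locus_id = ivs$variant_id[i], ...)
  })
  pp4 <- vapply(results, function(r) r$pp[["PP4"]], numeric(1))
  list(results = results,
       summary = list(any_coloc = any(pp4 > pp4_threshold),
                      fraction = mean(pp4 > pp4_threshold),
                      n_loci = length(pp4)))
}
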