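# Seeded generator of paired exposure/outcome GWAS summary statistics under
# fully known truth.
#
# Stated world: the exposure emulates a plasma-metabolite GWAS on the SD
# scale (default cohort size 14,296); the outcome emulates a case-control
# cancer GWAS on the log-odds scale (default 85,716 with 34.1% cases, the
# lung-cancer consortium shape). Per-variant effects are drawn so that
# instrument F statistics and variance explained land in the range reported
# for real metabolite instruments; see the methods vignette.

#' Simulation configuration
#'
#' @param n_snps Number of variants.
#' @param n_exp,n_out Exposure / outcome GWAS sample sizes.
#' @param k_cases Case fraction of the outcome GWAS, in (0,1).
#' @param theta True causal effect, log-odds per SD of exposure.
#' @param gamma_mean,gamma_sd Normal distribution of variant-exposure
#'   effects (SD units per allele).
#' @param gamma_min Minimum |effect|. When positive, effects are
#'   `sign(v) * (gamma_min + |v|)` with `v ~ N(gamma_mean, gamma_sd)` — a
#'   floor-plus-half-normal that guarantees instrument significance while
#'   keeping instrument strength well spread (0 disables the floor and the
#'   plain normal is used).
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"` direct
#'   variant-outcome effects.
#' @param pleio_mean,pleio_sd Mean / SD of the pleiotropic effects
#'   (log-odds); `pleio_mean` is forced to 0 for `"balanced"`.
#' @param outlier_frac Fraction of variants turned into outliers (< 0.5).
#' @param outlier_shift Outlier displacement in units of the variant's
#'   outcome SE, added to `beta_out` with the sign of the variant's exposure
#'   effect (so displaced Wald ratios share a direction, the classic
#'   directional-invalid-instrument construction).
#' @param reverse If `TRUE` the causal arrow is flipped: variants act on the
#'   outcome and the exposure inherits `theta` times the outcome effect.
#' @param ld_blocks Optional `list(block_size =, r2_within =)`; variants are
#'   grouped into blocks of `block_size` placed 50 kb apart within a block
#'   (blocks 2 Mb apart), and the emitted LD panel carries `r2_within` for
#'   same-block pairs. Affects the panel and positions only.
#' @param seed Integer seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 50, n_exp = 14296, n_out = 85716,
                       k_cases = 0.341, theta = 0,
                       gamma_mean = 0, gamma_sd = 0.2, gamma_min = 0.08,
                       pleiotropy = c("none", "balanced", "directional"),
                       pleio_mean = 0, pleio_sd = 0,
                       outlier_frac = 0, outlier_shift = 0,
                       reverse = FALSE, ld_blocks = NULL, seed) {
  pleiotropy <- match.arg(pleiotropy)
  assert_that(!missing(seed), "sim_config: seed is mandatory")
  assert_that(outlier_frac >= 0 && outlier_frac < 0.5,
              "sim_config: outlier_frac must be in [0, 0.5)")
  assert_that(k_cases > 0 && k_cases < 1, "sim_config: k_cases must be in (0,1)")
  if (pleiotropy == "balanced") pleio_mean <- 0
  structure(list(n_snps = n_snps, n_exp = n_exp, n_out = n_out,
                 k_cases = k_cases, theta = theta,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 gamma_min = gamma_min, pleiotropy = pleiotropy,
                 pleio_mean = pleio_mean, pleio_sd = pleio_sd,
                 outlier_frac = outlier_frac, outlier_shift = outlier_shift,
                 reverse = reverse, ld_blocks = ld_blocks,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @noRd
allele_pairs <- function(n, rng_ok = TRUE) {
  # non-palindromic pairs only
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2, byrow = TRUE)
  idx <- sample.int(4, n, replace = TRUE)
  list(ea = pairs[idx, 1], oa = pairs[idx, 2])
}

#' Simulate a paired exposure/outcome summary-statistic set
#'
#' Generates, under `cfg` and its seed:
#' `beta_exp_j = gamma_j + e_j` with `e_j ~ N(0, se_exp_j^2)`,
#' `se_exp_j = 1/sqrt(n_exp * 2 eaf_j (1-eaf_j))`;
#' `beta_out_j = theta * gamma_j + alpha_j + u_j` with the case-control
#' approximation `se_out_j = 1/sqrt(n_out * k (1-k) * 2 eaf_j (1-eaf_j))`;
#' outliers receive an extra `outlier_shift * se_out_j`; in reverse mode the
#' variants act on the outcome and the exposure inherits the causal effect.
#' EAFs are Uniform(0.10, 0.50); p-values from the normal approximation.
#'
#' @param cfg A [sim_config()].
#' @return `list(exposure, outcome, panel, truth)`; the tables are canonical
#'   summary-statistic data.frames, `panel` an [ld_panel()], `truth` a
#'   `sim_truth` list (`theta`, `gamma`, `alpha`, `outlier_ids`,
#'   `r2_expected`, `cfg`).
#' @export
simulate_pair <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  m <- cfg$n_snps
  ids <- sprintf("rs%06d", seq_len(m))
  eaf <- stats::runif(m, 0.10, 0.50)

  if (is.null(cfg$ld_blocks)) {
    # 2 Mb apart (independent at any clumping window), 500 variants per
    # chromosome to keep positions inside integer range
    chrom <- as.character(1 + (seq_len(m) - 1) %/% 500)
    pos <- as.integer((((seq_len(m) - 1) %% 500) + 1) * 2000000)
    r2 <- diag(1, m)
  } else {
    bs <- cfg$ld_blocks$block_size
    block <- (seq_len(m) - 1) %/% bs
    within <- (seq_len(m) - 1) %% bs
    chrom <- rep("1", m)
    pos <- as.integer(block * 2000000L + within * 50000L + 1L)
    same <- outer(block, block, `==`)
    r2 <- ifelse(same, cfg$ld_blocks$r2_within, 0)
    diag(r2) <- 1
  }
  panel <- ld_panel(ids, r2)

  u <- stats::rnorm(m)
  v <- cfg$gamma_mean + cfg$gamma_sd * u
  if (cfg$gamma_min > 0) {
    # floor + half-normal: |gamma| = gamma_min + |v|, sign of v. Avoids a
    # point mass at the floor (which would leave Egger weakly identified)
    # while guaranteeing instrument significance.
    g <- ifelse(v >= 0, 1, -1) * (cfg$gamma_min + abs(v))
  } else {
    g <- v
  }
  # pleiotropic effects are drawn on the oriented (exposure-increasing
  # allele) scale and applied with the instrument's sign, so "directional"
  # stays directional after harmonization orients beta_exp >= 0
  alpha_oriented <- switch(cfg$pleiotropy,
                           none = rep(0, m),
                           balanced = stats::rnorm(m, 0, cfg$pleio_sd),
                           directional = stats::rnorm(m, cfg$pleio_mean, cfg$pleio_sd))
  alpha <- alpha_oriented * ifelse(g >= 0, 1, -1)
  se_exp <- 1 / sqrt(cfg$n_exp * 2 * eaf * (1 - eaf))
  se_out <- 1 / sqrt(cfg$n_out * cfg$k_cases * (1 - cfg$k_cases) * 2 * eaf * (1 - eaf))

  n_outlier <- floor(cfg$outlier_frac * m)
  outlier_idx <- if (n_outlier > 0) sample.int(m, n_outlier) else integer(0)
  shift <- rep(0, m)
  # displacement is aligned with the instrument orientation (sign of gamma)
  # so that invalid instruments push the Wald ratios in a common direction
  shift[outlier_idx] <- cfg$outlier_shift * se_out[outlier_idx] *
    ifelse(g[outlier_idx] >= 0, 1, -1)

  if (!cfg$reverse) {
    mu_exp <- g
    mu_out <- cfg$theta * g + alpha + shift
  } else {
    mu_out <- g + alpha + shift
    mu_exp <- cfg$theta * g
  }
  beta_exp <- mu_exp + stats::rnorm(m, 0, se_exp)
  beta_out <- mu_out + stats::rnorm(m, 0, se_out)

  al <- allele_pairs(m)
  mk <- function(beta, se, n) {
    data.frame(variant_id = ids, chrom = chrom, pos = pos,
               effect_allele = al$ea, other_allele = al$oa, eaf = eaf,
               beta = beta, se = se,
               pvalue = 2 * stats::pnorm(-abs(beta / se)), n = n,
               stringsAsFactors = FALSE)
  }
  truth <- structure(list(theta = cfg$theta, gamma = g, alpha = alpha,
                          alpha_oriented = alpha_oriented,
                          outlier_ids = ids[outlier_idx],
                          r2_expected = mu_exp^2 / (mu_exp^2 + cfg$n_exp * se_exp^2),
                          cfg = cfg),
                     class = "sim_truth")
  list(exposure = mk(beta_exp, se_exp, cfg$n_exp),
       outcome = mk(beta_out, se_out, cfg$n_out),
       panel = panel, truth = truth)
}

#' Simulate regional statistics for colocalization
#'
#' One causal variant per trait (the same index iff `shared_causal`);
#' marginal z-scores decay to neighbours through an exponential LD
#' correlation `r(d) = exp(-d / ld_decay)` in index units, plus standard
#' normal noise. Betas are `z * se` with SEs from the trait sample sizes.
#'
#' @param shared_causal Share a single causal variant between the traits?
#' @param n_variants Locus size (>= 10).
#' @param z_causal Causal-variant z-score magnitude.
#' @param ld_decay Correlation decay length, in variant-index units.
#' @param seed Integer seed.
#' @param n1,n2 Effective sample sizes for the two traits (set SE scale).
#' @return `list(trait1, trait2, truth)`; traits carry `variant_id`,
#'   `chrom`, `pos`, `beta`, `se`.
#' @export
simulate_region <- function(shared_causal, n_variants = 200, z_causal = 12,
                            ld_decay = 10, seed, n1 = 14296, n2 = 85716) {
  assert_that(n_variants >= 10, "simulate_region: n_variants must be >= 10")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  ids <- sprintf("locus_rs%04d", seq_len(n_variants))
  pos <- seq_len(n_variants) * 2000L
  c1 <- n_variants %/% 2
  # distinct causal variants far apart relative to the decay length
  c2 <- if (shared_causal) c1 else max(1, c1 - round(8 * ld_decay))
  r_to <- function(c) exp(-abs(seq_len(n_variants) - c) / ld_decay)
  # noise must share the LD correlation of the signal, otherwise neighbouring
  # z-scores are mutually inconsistent; AR(1) noise matches the exponential
  # correlation decay exactly
  ar1_noise <- function() {
    phi <- exp(-1 / ld_decay)
    e <- numeric(n_variants)
    e[1] <- stats::rnorm(1)
    for (i in seq_len(n_variants - 1)) {
      e[i + 1] <- phi * e[i] + sqrt(1 - phi^2) * stats::rnorm(1)
    }
    e
  }
  z1 <- r_to(c1) * z_causal + ar1_noise()
  z2 <- r_to(c2) * z_causal + ar1_noise()
  eaf <- stats::runif(n_variants, 0.1, 0.5)
  se1 <- 1 / sqrt(n1 * 2 * eaf * (1 - eaf))
  se2 <- 1 / sqrt(n2 * 0.25 * 2 * eaf * (1 - eaf))
  mk <- function(z, se) data.frame(variant_id = ids, chrom = "1", pos = pos,
                                   beta = z * se, se = se, stringsAsFactors = FALSE)
  list(trait1 = mk(z1, se1), trait2 = mk(z2, se2),
       truth = list(shared = shared_causal, causal1 = ids[c1], causal2 = ids[c2]))
}

#' Named scenario presets
#'
#' Stable set of generator configurations covering the pipeline's failure
#' modes. Each preset documents its expected behaviour:
#' \describe{
#'   \item{null}{theta = 0, valid instruments; IVW type-I error nominal.}
#'   \item{causal}{theta = 0.2, 50 strong valid instruments; all four
#'     estimators recover theta.}
#'   \item{balanced_pleiotropy}{direct outcome effects with mean 0; Egger
#'     intercept centred at 0, heterogeneity inflated.}
#'   \item{directional_pleiotropy}{direct effects with mean 0.03 log-odds;
#'     Egger intercept centred at the mean, confidence ledger fails the
#'     no-pleiotropy criterion.}
#'   \item{outliers}{10% of instruments displaced by 8 outcome SEs; the
#'     outlier test flags them.}
#'   \item{weak_instruments}{tiny variant-exposure effects; most instruments
#'     fall below F = 10.}
#'   \item{reverse_causal}{outcome causes exposure; the Steiger filter
#'     strips the instrument set.}
#'   \item{two_cohort_replication}{carries `n_exp2 = 8192` for a second
#'     exposure cohort via [simulate_two_cohorts()].}
#' }
#'
#' @param seed Master seed; each preset receives a derived child seed.
#' @return Named list of `sim_config` objects.
#' @export
scenario_presets <- function(seed = 1L) {
  s <- function(k) derive_seed(seed, k)
  presets <- list(
    null = sim_config(n_snps = 30, theta = 0, seed = s(1)),
    # wide instrument-strength spread: the regime in which Egger regression
    # is well identified (its slope attenuates as strength homogenizes)
    causal = sim_config(n_snps = 50, theta = 0.2, gamma_sd = 0.3, seed = s(2)),
    balanced_pleiotropy = sim_config(n_snps = 50, theta = 0.2,
                                     pleiotropy = "balanced", pleio_sd = 0.02,
                                     seed = s(3)),
    directional_pleiotropy = sim_config(n_snps = 50, theta = 0.2,
                                        pleiotropy = "directional",
                                        pleio_mean = 0.03, pleio_sd = 0.01,
                                        seed = s(4)),
    outliers = sim_config(n_snps = 50, theta = 0.2, outlier_frac = 0.1,
                          outlier_shift = 8, seed = s(5)),
    weak_instruments = sim_config(n_snps = 50, theta = 0.1, gamma_sd = 0.015,
                                  gamma_min = 0, seed = s(6)),
    reverse_causal = sim_config(n_snps = 50, theta = 0.3, reverse = TRUE,
                                seed = s(7)),
    two_cohort_replication = sim_config(n_snps = 50, theta = 0.2, seed = s(8))
  )
  presets$two_cohort_replication$n_exp2 <- 8192
  presets
}

#' Two-cohort replication simulation
#'
#' Re-uses the variant-exposure truth of `cfg` to emit a second, independent
#' exposure cohort of size `n_exp2` (default from the preset, else 8192),
#' emulating discovery + replication metabolite GWAS sharing genetics but
#' not noise.
#'
#' @param cfg A `sim_config` (optionally carrying `n_exp2`).
#' @return `list(discovery, replication)` of [simulate_pair()]-shaped lists
#'   sharing `truth$gamma` and the outcome table.
#' @export
simulate_two_cohorts <- function(cfg) {
  first <- simulate_pair(cfg)
  n2 <- cfg$n_exp2 %||% 8192
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, 99))
  e <- first$exposure
  se2 <- 1 / sqrt(n2 * 2 * e$eaf * (1 - e$eaf))
  beta2 <- first$truth$gamma + stats::rnorm(nrow(e), 0, se2)
  rep_exp <- e
  rep_exp$beta <- beta2
  rep_exp$se <- se2
  rep_exp$pvalue <- 2 * stats::pnorm(-abs(beta2 / se2))
  rep_exp$n <- n2
  second <- list(exposure = rep_exp, outcome = first$outcome,
                 panel = first$panel, truth = first$truth)
  list(discovery = first, replication = second)
}
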