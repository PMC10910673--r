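# Instrument selection: MAF filter, LD clumping, R2/F, weak-instrument and
# Steiger directionality filtering.

#' Clumping / instrument-selection configuration
#'
#' Bundles every threshold used during instrument selection. Two named
#' profiles are provided: `"primary"` (exposure-significant variants at
#' P < 1e-6, pairwise LD r2 < 0.1 within a 500 kb window) and `"stringent"`
#' (P < 5e-8, r2 < 0.001, 1000 kb window) which is also the reverse-MR
#' profile. Both keep `maf_min = 0.05`, `f_min = 10` and require at least
#' 3 surviving instruments.
#'
#' @param profile `"primary"` or `"stringent"`; starting values for the
#'   thresholds, individually overridable.
#' @param p_threshold,r2_threshold,window_kb,maf_min,f_min,min_ivs Overrides.
#' @return A `clump_config` list.
#' @export
clump_config <- function(profile = c("primary", "stringent"),
                         p_threshold = NULL, r2_threshold = NULL,
                         window_kb = NULL, maf_min = 0.05, f_min = 10,
                         min_ivs = 3) {
  profile <- match.arg(profile)
  base <- switch(profile,
    primary = list(p_threshold = 1e-6, r2_threshold = 0.1, window_kb = 500),
    stringent = list(p_threshold = 5e-8, r2_threshold = 0.001, window_kb = 1000))
  cfg <- list(
    profile = profile,
    p_threshold = p_threshold %||% base$p_threshold,
    r2_threshold = r2_threshold %||% base$r2_threshold,
    window_kb = window_kb %||% base$window_kb,
    maf_min = maf_min,
    f_min = f_min,
    min_ivs = min_ivs
  )
  assert_that(cfg$p_threshold > 0 && cfg$p_threshold < 1,
              "clump_config: p_threshold must be in (0,1)")
  assert_that(cfg$r2_threshold >= 0 && cfg$r2_threshold <= 1,
              "clump_config: r2_threshold must be in [0,1]")
  assert_that(cfg$window_kb > 0, "clump_config: window_kb must be positive")
  structure(cfg, class = "clump_config")
}

#' LD panel of pairwise r-squared values
#'
#' @param variant_ids Character vector of variant identifiers.
#' @param r2 Symmetric matrix of pairwise LD r2 in `[0,1]` with unit
#'   diagonal, dimensions matching `variant_ids`.
#' @return An `ld_panel` object.
#' @export
ld_panel <- function(variant_ids, r2) {
  r2 <- as.matrix(r2)
  assert_that(nrow(r2) == length(variant_ids) && ncol(r2) == length(variant_ids),
              "ld_panel: matrix dimensions do not match variant_ids")
  assert_that(all(abs(r2 - t(r2)) < 1e-12), "ld_panel: r2 matrix must be symmetric")
  assert_that(all(abs(diag(r2) - 1) < 1e-12), "ld_panel: diagonal must be 1")
  assert_that(all(r2 >= 0 & r2 <= 1), "ld_panel: r2 values must be in [0,1]")
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids, r2 = r2), class = "ld_panel")
}

#' Read an LD panel from TSV
#'
#' Accepts either a square matrix TSV (header row and first column carry the
#' variant ids) or a 3-column long format `id1 id2 r2`; pairs absent from a
#' long-format file are taken as r2 = 0.
#' @param path TSV path.
#' @export
read_ld_panel <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  is_square <- all(names(dt)[-1] %in% as.character(dt[[1]]))
  if (!is_square && ncol(dt) == 3 && is.numeric(dt[[3]])) {
    ids <- sort(unique(c(as.character(dt[[1]]), as.character(dt[[2]]))))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    i <- match(as.character(dt[[1]]), ids)
    j <- match(as.character(dt[[2]]), ids)
    m[cbind(i, j)] <- dt[[3]]
    m[cbind(j, i)] <- dt[[3]]
    return(ld_panel(ids, m))
  }
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  ld_panel(ids, m)
}

#' Pairwise LD r-squared from a genotype-dosage matrix
#'
#' Auxiliary helper: squared Pearson correlation between dosage columns.
#' @param dosages Numeric matrix, one column per variant (colnames = ids).
#' @export
ld_from_dosage <- function(dosages) {
  r <- stats::cor(dosages)
  ld_panel(colnames(dosages), r * r)
}

#' Variance explained by a single variant
#'
#' `R2 = (2 b^2 EAF (1-EAF)) / (2 b^2 EAF (1-EAF) + 2 N EAF (1-EAF) SE^2)`,
#' which algebraically reduces to `b^2 / (b^2 + N SE^2)` (independent of
#' EAF); the full form is evaluated as printed. Vectorized.
#'
#' @param beta,eaf,se,n Per-variant effect, effect-allele frequency in (0,1),
#'   standard error (> 0) and GWAS sample size (> 2).
#' @return R-squared fraction in `[0, 1)`.
#' @export
compute_r2 <- function(beta, eaf, se, n) {
  assert_that(all(is.finite(beta) & is.finite(eaf) & is.finite(se) & is.finite(n)),
              "computation error: non-finite input to compute_r2")
  assert_that(all(eaf > 0 & eaf < 1), "computation error: eaf must be in (0,1)")
  assert_that(all(se > 0), "computation error: se must be > 0")
  assert_that(all(n > 2), "computation error: n must exceed 2")
  num <- 2 * beta^2 * eaf * (1 - eaf)
  num / (num + 2 * n * eaf * (1 - eaf) * se^2)
}

#' Instrument-strength F statistic
#'
#' `F = R2 (N - 2) / (1 - R2)`. Vectorized.
#' @param r2 Variance explained in `[0, 1)`.
#' @param n GWAS sample size (> 2).
#' @export
compute_f <- function(r2, n) {
  assert_that(all(is.finite(r2) & is.finite(n)), "computation error: non-finite input to compute_f")
  assert_that(all(r2 >= 0 & r2 < 1), "computation error: r2 must be in [0,1)")
  assert_that(all(n > 2), "computation error: n must exceed 2")
  r2 * (n - 2) / (1 - r2)
}

#' Greedy LD clumping
#'
#' Candidates passing the significance threshold are visited in order of
#' ascending p-value (ties broken by chromosome, position, then variant id);
#' a candidate is accepted iff its LD r2 with every already-accepted variant
#' on the same chromosome within `window_kb` kilobases is below
#' `r2_threshold`. Cross-chromosome pairs, pairs beyond the window, and
#' variants absent from the panel (logged) are treated as independent.
#'
#' @param candidates data.frame with `variant_id`, `chrom`, `pos`, `pvalue`.
#' @param panel An [ld_panel()] (or `NULL` for a fully independent panel).
#' @param cfg A [clump_config()].
#' @return Character vector of accepted variant ids, in acceptance order.
#' @export
ld_clump <- function(candidates, panel, cfg = clump_config()) {
  x <- candidates[!is.na(candidates$pvalue) & candidates$pvalue < cfg$p_threshold, , drop = FALSE]
  if (nrow(x) == 0) return(character(0))
  ord <- order(x$pvalue, x$chrom, x$pos, x$variant_id)
  x <- x[ord, , drop = FALSE]
  in_panel <- if (is.null(panel)) rep(FALSE, nrow(x)) else x$variant_id %in% panel$variant_ids
  if (any(!in_panel) && !is.null(panel)) {
    msg("ld_clump: %d candidate(s) absent from LD panel, treated as independent", sum(!in_panel))
  }
  accepted <- integer(0)
  window_bp <- cfg$window_kb * 1000
  for (i in seq_len(nrow(x))) {
    ok <- TRUE
    for (j in accepted) {
      same_chr <- !is.na(x$chrom[i]) && !is.na(x$chrom[j]) && x$chrom[i] == x$chrom[j]
      if (!same_chr) next
      if (is.na(x$pos[i]) || is.na(x$pos[j]) || abs(x$pos[i] - x$pos[j]) > window_bp) next
      if (!in_panel[i] || !in_panel[j]) next
      if (panel$r2[x$variant_id[i], x$variant_id[j]] >= cfg$r2_threshold) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  x$variant_id[accepted]
}

#' Steiger directionality filter
#'
#' Keeps an instrument iff it explains more variance in the exposure than in
#' the outcome (`r2_exp > r2_out`) and the one-sided independent-samples
#' comparison of the Fisher-transformed correlations `sqrt(r2_exp)` vs
#' `sqrt(r2_out)` (cohort sizes `n_exp`, `n_out`) is significant at
#' `alpha`. Instruments whose outcome association explains as much or more
#' variance are the signature of reverse causation and are removed.
#'
#' @param ivs A `harmonized_ivs` data.frame with `r2_exp` and `r2_out`.
#' @param n_exp,n_out Exposure / outcome GWAS sample sizes.
#' @param alpha One-sided significance level (default 0.05).
#' @return `list(kept = harmonized_ivs, removed = character vector of ids)`.
#' @export
steiger_filter <- function(ivs, n_exp, n_out, alpha = 0.05) {
  if (nrow(ivs) == 0) return(list(kept = ivs, removed = character(0)))
  z1 <- atanh(pmin(sqrt(pmax(ivs$r2_exp, 0)), 1 - 1e-12))
  z2 <- atanh(pmin(sqrt(pmax(ivs$r2_out, 0)), 1 - 1e-12))
  zstat <- (z1 - z2) / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  p_one_sided <- stats::pnorm(zstat, lower.tail = FALSE)
  keep <- ivs$r2_exp > ivs$r2_out & p_one_sided < alpha
  removed <- ivs$variant_id[!keep]
  if (length(removed)) msg("steiger_filter: removed %d instrument(s)", length(removed))
  kept <- ivs[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}

#' Select instruments for one exposure-outcome pair
#'
#' Applies, in order: minor-allele-frequency filter (on the folded
#' exposure-study EAF), harmonization (outcome presence, palindrome
#' exclusion, allele alignment), exposure significance + greedy LD clumping,
#' weak-instrument exclusion (`F >= f_min`), the Steiger directionality
#' filter, and optionally one simulation-based outlier-removal pass
#' ([presso_outlier()]). Returns an empty set with a recorded `reason`
#' attribute when fewer than `cfg$min_ivs` instruments survive.
#'
#' @param exposure,outcome Canonical summary-statistic data.frames; the
#'   exposure must carry `eaf`, `pvalue`, `chrom`, `pos` and `n`.
#' @param panel [ld_panel()] or `NULL`.
#' @param cfg [clump_config()].
#' @param presso_n_sim Number of outlier-test simulations for the optional
#'   post-selection outlier pass; `0` (default) disables the pass.
#' @param seed Seed for the outlier pass (required when `presso_n_sim > 0`).
#' @return A `harmonized_ivs` data.frame (possibly empty) with attributes
#'   `selection_log` (named drop counts) and, when empty, `reason`.
#' @export
select_instruments <- function(exposure, outcome, panel, cfg = clump_config(),
                               presso_n_sim = 0, seed = NULL) {
  log <- list()
  fail <- function(ivs, reason) {
    empty <- ivs[0, , drop = FALSE]
    attr(empty, "selection_log") <- log
    attr(empty, "reason") <- reason
    msg("select_instruments: %s", reason)
    empty
  }

  maf <- pmin(exposure$eaf, 1 - exposure$eaf)
  keep <- !is.na(maf) & maf > cfg$maf_min
  log$n_input <- nrow(exposure)
  log$n_maf_fail <- sum(!keep)
  exposure <- exposure[keep, , drop = FALSE]

  ivs <- harmonize(exposure, outcome)
  log$harmonize <- as.list(attr(ivs, "counts"))

  sig <- !is.na(ivs$pvalue_exp) & ivs$pvalue_exp < cfg$p_threshold
  log$n_not_significant <- sum(!sig)
  if (!any(sig)) return(fail(ivs, "no significant variants"))
  cand <- data.frame(variant_id = ivs$variant_id[sig], chrom = ivs$chrom[sig],
                     pos = ivs$pos[sig], pvalue = ivs$pvalue_exp[sig],
                     stringsAsFactors = FALSE)
  kept_ids <- ld_clump(cand, panel, cfg)
  log$n_clumped_away <- sum(sig) - length(kept_ids)
  ivs <- ivs[match(kept_ids, ivs$variant_id), , drop = FALSE]

  weak <- ivs$f_stat < cfg$f_min
  log$n_weak <- sum(weak)
  ivs <- ivs[!weak, , drop = FALSE]
  if (nrow(ivs) < cfg$min_ivs) {
    return(fail(ivs, sprintf("fewer than %d instruments after F filter", cfg$min_ivs)))
  }

  n_exp <- stats::median(ivs$n_exp, na.rm = TRUE)
  n_out <- stats::median(ivs$n_out, na.rm = TRUE)
  st <- steiger_filter(ivs, n_exp, n_out)
  log$n_steiger <- length(st$removed)
  ivs <- st$kept
  if (nrow(ivs) < cfg$min_ivs) {
    return(fail(ivs, sprintf("fewer than %d instruments after Steiger filter", cfg$min_ivs)))
  }

  if (presso_n_sim > 0 && nrow(ivs) >= 4) {
    assert_that(!is.null(seed), "select_instruments: seed required when presso_n_sim > 0")
    out <- presso_outlier(ivs, n_sim = presso_n_sim, seed = seed)
    flagged <- out$variant_id[out$p_bonferroni < 0.05]
    log$n_presso_outliers <- length(flagged)
    ivs <- ivs[!ivs$variant_id %in% flagged, , drop = FALSE]
    if (nrow(ivs) < cfg$min_ivs) {
      return(fail(ivs, sprintf("fewer than %d instruments after outlier removal", cfg$min_ivs)))
    }
  }

  rownames(ivs) <- NULL
  attr(ivs, "selection_log") <- log
  class(ivs) <- c("harmonized_ivs", "data.frame")
  ivs
}
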