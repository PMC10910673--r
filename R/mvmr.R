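# Multivariable MR: direct effects of co-modelled exposures.

#' Assemble a multivariable MR input
#'
#' @param iv_ids Character vector of instrument ids (unique).
#' @param exposure_betas Numeric matrix, instruments x exposures, with
#'   exposure ids as column names.
#' @param exposure_ses Matrix of matching standard errors.
#' @param outcome_betas,outcome_ses Numeric vectors, one entry per
#'   instrument.
#' @return An `mvmr_input` list.
#' @export
mvmr_input <- function(iv_ids, exposure_betas, exposure_ses,
                       outcome_betas, outcome_ses) {
  exposure_betas <- as.matrix(exposure_betas)
  exposure_ses <- as.matrix(exposure_ses)
  k <- length(iv_ids)
  assert_that(!anyDuplicated(iv_ids), "mvmr_input: duplicate instrument ids")
  assert_that(nrow(exposure_betas) == k && length(outcome_betas) == k &&
                length(outcome_ses) == k && all(dim(exposure_ses) == dim(exposure_betas)),
              "mvmr_input: dimension mismatch")
  assert_that(!is.null(colnames(exposure_betas)),
              "mvmr_input: exposure_betas needs column names (exposure ids)")
  assert_that(all(colSums(exposure_betas != 0) > 0),
              "mvmr_input: all-zero exposure column")
  structure(list(iv_ids = iv_ids, exposure_betas = exposure_betas,
                 exposure_ses = exposure_ses, outcome_betas = outcome_betas,
                 outcome_ses = outcome_ses), class = "mvmr_input")
}

#' Build a multivariable input from per-exposure instrument sets
#'
#' Takes the union of instruments across the supplied harmonized sets
#' (deduplicated by variant id); an exposure beta missing for an instrument
#' (variant not instrumenting that exposure) is imputed as 0 with a logged
#' count — a documented assumption, see the methods vignette.
#'
#' @param ivsets Named list of `harmonized_ivs` data.frames, one per
#'   exposure, all harmonized against the same outcome.
#' @return An `mvmr_input`.
#' @export
mvmr_from_ivsets <- function(ivsets) {
  assert_that(length(ivsets) >= 1 && !is.null(names(ivsets)),
              "mvmr_from_ivsets: named list required")
  ids <- unique(unlist(lapply(ivsets, `[[`, "variant_id")))
  p <- length(ivsets)
  B <- matrix(0, length(ids), p, dimnames = list(ids, names(ivsets)))
  S <- matrix(NA_real_, length(ids), p, dimnames = list(ids, names(ivsets)))
  yb <- ys <- stats::setNames(rep(NA_real_, length(ids)), ids)
  n_imputed <- 0L
  for (e in names(ivsets)) {
    iv <- ivsets[[e]]
    B[iv$variant_id, e] <- iv$beta_exp
    S[iv$variant_id, e] <- iv$se_exp
    yb[iv$variant_id] <- iv$beta_out
    ys[iv$variant_id] <- iv$se_out
    n_imputed <- n_imputed + (length(ids) - nrow(iv))
  }
  # SEs for zero-imputed cells: median of the exposure's observed SEs
  for (e in seq_len(p)) S[is.na(S[, e]), e] <- stats::median(S[, e], na.rm = TRUE)
  if (n_imputed > 0) msg("mvmr_from_ivsets: zero-imputed %d missing exposure beta(s)", n_imputed)
  inp <- mvmr_input(ids, B, S, unname(yb), unname(ys))
  attr(inp, "n_imputed") <- n_imputed
  inp
}

#' Multivariable IVW
#'
#' Weighted least squares of the outcome effects on the exposure-effect
#' matrix without intercept, weights `1/outcome_se^2`. Each coefficient is
#' the exposure's direct effect on the outcome conditional on the other
#' exposures. SEs use the multiplicative random-effects inflation
#' `max(1, sqrt(Q / (n_iv - n_exposures)))`; p-values from the normal
#' approximation.
#'
#' @param input An `mvmr_input`.
#' @return data.frame: `exposure_id`, `beta`, `se`, `or_`, `ci_low`,
#'   `ci_high`, `pvalue`; attributes `q_stat`, `q_df`.
#' @export
mvmr_ivw <- function(input) {
  X <- input$exposure_betas
  y <- input$outcome_betas
  w <- 1 / input$outcome_ses^2
  k <- nrow(X); p <- ncol(X)
  assert_that(k > p + 1, "mvmr_ivw: need n_iv > n_exposures + 1")
  Xw <- X * sqrt(w); yw <- y * sqrt(w)
  qr_x <- qr(Xw)
  if (qr_x$rank < p) {
    dep <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1, p)]]
    stop(sprintf("collinearity error: dependent exposure column(s): %s",
                 paste(dep, collapse = ", ")), call. = FALSE)
  }
  XtX <- crossprod(Xw)
  beta <- drop(solve(XtX, crossprod(Xw, yw)))
  resid <- y - drop(X %*% beta)
  q <- sum(w * resid^2)
  phi <- max(1, sqrt(q / (k - p)))
  se <- sqrt(diag(solve(XtX))) * phi
  z <- beta / se
  out <- data.frame(exposure_id = colnames(X), beta = beta, se = se,
                    or_ = exp(beta),
                    ci_low = exp(beta - stats::qnorm(0.975) * se),
                    ci_high = exp(beta + stats::qnorm(0.975) * se),
                    pvalue = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "q_stat") <- q
  attr(out, "q_df") <- k - p
  out
}

#' Conditional instrument strength
#'
#' For each exposure, its instrument effects are regressed (ordinary least
#' squares, no intercept) on the other exposures' instrument effects; the
#' conditional strength is the mean excess of the squared residual over its
#' sampling noise, `cF_k = max(0, mean(resid^2 / se^2) - 1)`. Orthogonal
#' strong instruments give cF close to the mean univariable F; perfectly
#' collinear exposures give cF near 0.
#'
#' @param input An `mvmr_input`.
#' @return data.frame: `exposure_id`, `conditional_f`.
#' @export
conditional_f <- function(input) {
  X <- input$exposure_betas
  S <- input$exposure_ses
  p <- ncol(X)
  cf <- vapply(seq_len(p), function(j) {
    xj <- X[, j]
    if (p == 1) {
      resid <- xj
    } else {
      Z <- X[, -j, drop = FALSE]
      fit <- stats::lm.fit(Z, xj)
      resid <- fit$residuals
    }
    max(0, mean(resid^2 / S[, j]^2) - 1)
  }, numeric(1))
  data.frame(exposure_id = colnames(X), conditional_f = cf,
             stringsAsFactors = FALSE)
}
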