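# Internal numeric and logging helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when they are numerically equal
#' @noRd
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' @noRd
msg <- function(...) {
  if (isTRUE(getOption("mrscreen.quiet", TRUE))) return(invisible(NULL))
  message(sprintf(...))
}

#' @noRd
assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# deterministic child seeds derived from a master seed, kept below 2^31
#' @noRd
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 + k * 2654435761) %% 2147483647)
}
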