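# Shared fixture builders. Everything is generated in code; no binary data.

# canonical summary-stat row(s)
ss_row <- function(id, ea = "A", oa = "G", beta = 0.1, se = 0.01, eaf = 0.3,
                   chrom = "1", pos = 1e6, pvalue = NULL, n = 14296) {
  data.frame(variant_id = id, chrom = chrom, pos = as.integer(pos),
             effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
             se = se,
             pvalue = if (is.null(pvalue)) 2 * pnorm(-abs(beta / se)) else pvalue,
             n = n, stringsAsFactors = FALSE)
}

# a bare harmonized IV table with chosen Wald ratios
make_ivs <- function(ratios, beta_exp = 0.1, se_exp = 0.005, se_out = 0.02,
                     ids = sprintf("iv%02d", seq_along(ratios))) {
  k <- length(ratios)
  beta_exp <- rep_len(beta_exp, k)
  data.frame(variant_id = ids, chrom = "1", pos = as.integer(seq_len(k) * 1e6),
             beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
             beta_out = ratios * beta_exp, se_out = rep_len(se_out, k),
             eaf = 0.3, stringsAsFactors = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(df, path, sep = "\t")
  path
}

# Independent clumping oracle: the greedy result equals the
# lexicographically-first maximal independent set of the conflict graph
# under the p-value ordering. Enumerates all 2^n subsets (n <= 12).
oracle_clump <- function(candidates, panel, cfg) {
  x <- candidates[!is.na(candidates$pvalue) & candidates$pvalue < cfg$p_threshold, , drop = FALSE]
  if (nrow(x) == 0) return(character(0))
  x <- x[order(x$pvalue, x$chrom, x$pos, x$variant_id), , drop = FALSE]
  n <- nrow(x)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (is.na(x$chrom[i]) || is.na(x$chrom[j]) || x$chrom[i] != x$chrom[j]) next
    if (abs(x$pos[i] - x$pos[j]) > cfg$window_kb * 1000) next
    if (!(x$variant_id[i] %in% panel$variant_ids) ||
        !(x$variant_id[j] %in% panel$variant_ids)) next
    if (panel$r2[x$variant_id[i], x$variant_id[j]] >= cfg$r2_threshold) {
      conflict[i, j] <- TRUE
    }
  }
  best <- NULL
  for (mask in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) == 0) next
    if (any(conflict[members, members])) next
    maximal <- all(vapply(setdiff(seq_len(n), members), function(v) {
      any(conflict[v, members])
    }, logical(1)))
    if (!maximal) next
    # lexicographic order on sorted member indices (p-ordered)
    if (is.null(best)) { best <- members; next }
    a <- members; b <- best
    len <- min(length(a), length(b))
    cmp <- which(a[seq_len(len)] != b[seq_len(len)])
    if (length(cmp) > 0) {
      if (a[cmp[1]] < b[cmp[1]]) best <- members
    } else if (length(a) > length(b)) best <- members
  }
  x$variant_id[sort(best)]
}

# random clumping instance on one or two chromosomes
random_clump_instance <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  chrom <- sample(c("1", "2"), n, replace = TRUE, prob = c(0.8, 0.2))
  pos <- as.integer(sample.int(1200, n) * 1000)
  pvalue <- 10^-runif(n, 2, 12)
  # random symmetric r2 with some high-LD pairs
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- sample(c(0, 0.05, 0.3, 0.8), n * (n - 1) / 2,
                            replace = TRUE, prob = c(0.4, 0.2, 0.2, 0.2))
  m <- m + t(m); diag(m) <- 1
  list(candidates = data.frame(variant_id = ids, chrom = chrom, pos = pos,
                               pvalue = pvalue, stringsAsFactors = FALSE),
       panel = ld_panel(ids, m))
}
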