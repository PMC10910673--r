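# Reading, validating and harmonizing GWAS summary-statistic tables.
#
# A summary-statistic table is a plain data.frame with one row per variant and
# the canonical columns
#   variant_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
#   pvalue, n
# beta is on the trait scale: SD units for a quantitative exposure, log-odds
# for a binary outcome.

.SUMSTATS_REQUIRED <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
.SUMSTATS_OPTIONAL <- c("chrom", "pos", "eaf", "pvalue", "n")
.VALID_ALLELES <- c("A", "C", "G", "T")

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited (tab or comma, optionally gzipped) summary-statistic
#' table, renames columns to the canonical schema through `column_map`,
#' upper-cases alleles and drops rows that violate the per-variant invariants
#' (`se > 0`, `eaf` strictly inside (0,1) when present, `pvalue` in (0,1]
#' when present, `pos >= 1`, distinct A/C/G/T alleles). The number of dropped
#' rows is recorded in the `"n_dropped"` attribute and reported via
#' `message()` when `options(mrscreen.quiet = FALSE)`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector or list mapping canonical column
#'   names (e.g. `beta`) to the names used in the file (e.g. `Effect`).
#'   Canonical names absent from the map are looked up verbatim.
#' @param trait_kind `"quantitative"` or `"binary"`; stored as an attribute,
#'   downstream effect sizes are interpreted accordingly.
#' @return A `data.frame` with the canonical columns (missing optional
#'   columns filled with `NA`), attributes `trait_kind` and `n_dropped`.
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_kind = c("quantitative", "binary")) {
  trait_kind <- match.arg(trait_kind)
  assert_that(file.exists(path), "input error: file not found: %s", path)
  dt <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r"); on.exit(close(con), add = TRUE)
    data.table::fread(text = readLines(con), header = TRUE, data.table = FALSE)
  } else {
    data.table::fread(path, header = TRUE, data.table = FALSE)
  }
  assert_that(nrow(dt) > 0, "input error: empty summary-statistic file: %s", path)

  cmap <- as.list(column_map %||% list())
  resolve <- function(canon) {
    nm <- cmap[[canon]] %||% canon
    if (nm %in% names(dt)) nm else NA_character_
  }
  for (canon in .SUMSTATS_REQUIRED) {
    src <- resolve(canon)
    assert_that(!is.na(src),
                "configuration error: required column '%s' not found (looked for '%s')",
                canon, cmap[[canon]] %||% canon)
  }

  out <- data.frame(variant_id = as.character(dt[[resolve("variant_id")]]),
                    stringsAsFactors = FALSE)
  grab <- function(canon, as_fun) {
    src <- resolve(canon)
    if (is.na(src)) rep(NA, nrow(dt)) else as_fun(dt[[src]])
  }
  out$chrom <- grab("chrom", as.character)
  out$pos <- grab("pos", as.integer)
  out$effect_allele <- toupper(as.character(dt[[resolve("effect_allele")]]))
  out$other_allele <- toupper(as.character(dt[[resolve("other_allele")]]))
  out$eaf <- grab("eaf", as.numeric)
  out$beta <- as.numeric(dt[[resolve("beta")]])
  out$se <- as.numeric(dt[[resolve("se")]])
  out$pvalue <- grab("pvalue", as.numeric)
  out$n <- grab("n", as.numeric)

  ok <- validate_sumstats(out)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) msg("read_sumstats: dropped %d invalid row(s) from %s", n_dropped, path)
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait_kind") <- trait_kind
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @noRd
validate_sumstats <- function(x) {
  ok <- !is.na(x$variant_id) & nzchar(x$variant_id) &
    x$effect_allele %in% .VALID_ALLELES &
    x$other_allele %in% .VALID_ALLELES &
    x$effect_allele != x$other_allele &
    is.finite(x$beta) & is.finite(x$se) & x$se > 0
  ok <- ok & (is.na(x$eaf) | (x$eaf > 0 & x$eaf < 1))
  ok <- ok & (is.na(x$pvalue) | (x$pvalue > 0 & x$pvalue <= 1))
  ok <- ok & (is.na(x$pos) | x$pos >= 1)
  ok
}

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous-strand) variant carries complementary alleles:
#' \{A,T\} or \{C,G\}. Vectorized.
#'
#' @param effect_allele,other_allele Single-base alleles (A/C/G/T).
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele)
  b <- toupper(other_allele)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' @noRd
flip_strand <- function(allele) {
  chartr("ACGT", "TGCA", toupper(allele))
}

#' Harmonize exposure and outcome summary statistics into instruments
#'
#' Restricts to variants present in both tables, excludes palindromic
#' variants, aligns the outcome effect to the exposure's effect allele
#' (sign-flipping the outcome beta when alleles are swapped, attempting an
#' A<->T / C<->G strand flip before dropping incompatible pairs), and orients
#' every instrument so that `beta_exp >= 0` (flipping both betas and
#' complementing the effect-allele frequency otherwise). Per-variant
#' R-squared and F statistics are filled from [compute_r2()] / [compute_f()].
#'
#' Exposure-study EAF and sample size are used for R-squared and F; variants
#' without an exposure EAF are dropped (R-squared would be incomputable).
#'
#' @param exposure,outcome Canonical summary-statistic data.frames (see
#'   [read_sumstats()]); `variant_id` must be unique within each table.
#' @return A `harmonized_ivs` data.frame with columns `variant_id`, `chrom`,
#'   `pos`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf`, `pvalue_exp`,
#'   `n_exp`, `n_out`, `r2_exp`, `r2_out`, `f_stat`, and an attribute
#'   `counts` recording drops at each step.
#' @export
harmonize <- function(exposure, outcome) {
  dup_e <-unique(exposure$variant_id[duplicated(exposure$variant_id)])
  dup_o <- unique(outcome$variant_id[duplicated(outcome$variant_id)])
  assert_that(length(dup_e) == 0,
              "input error: duplicate variant_id in exposure: %s",
              paste(utils::head(dup_e, 5), collapse = ", "))
  assert_that(length(dup_o) == 0,
              "input error: duplicate variant_id in outcome: %s",
              paste(utils::head(dup_o, 5), collapse = ", "))

  common <- intersect(exposure$variant_id, outcome$variant_id)
  e <- exposure[match(common, exposure$variant_id), , drop = FALSE]
  o <- outcome[match(common, outcome$variant_id), , drop = FALSE]
  n_common <- length(common)

  pal <- is_palindromic(e$effect_allele, e$other_allele) |
    is_palindromic(o$effect_allele, o$other_allele)
  e <- e[!pal, , drop = FALSE]; o <- o[!pal, , drop = FALSE]
  n_palindromic <- sum(pal)

  # allele alignment: direct, swapped, then strand-flip rescue
  direct <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swapped <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
  need_flip <- !direct & !swapped
  if (any(need_flip)) {
    fe <- flip_strand(o$effect_allele[need_flip])
    fo <- flip_strand(o$other_allele[need_flip])
    d2 <- fe == e$effect_allele[need_flip] & fo == e$other_allele[need_flip]
    s2 <- fe == e$other_allele[need_flip] & fo == e$effect_allele[need_flip]
    direct[need_flip] <- d2
    swapped[need_flip] <- s2
  }
  keep <- direct | swapped
  n_incompatible <- sum(!keep)
  e <- e[keep, , drop = FALSE]; o <- o[keep, , drop = FALSE]
  swapped <- swapped[keep]

  beta_out <- ifelse(swapped, -o$beta, o$beta)

  miss_eaf <- is.na(e$eaf)
  n_missing_eaf <- sum(miss_eaf)
  e <- e[!miss_eaf, , drop = FALSE]; o <- o[!miss_eaf, , drop = FALSE]
  beta_out <- beta_out[!miss_eaf]

  # orient to beta_exp >= 0
  neg <- e$beta < 0
  beta_exp <- ifelse(neg, -e$beta, e$beta)
  beta_out <- ifelse(neg, -beta_out, beta_out)
  eaf <- ifelse(neg, 1 - e$eaf, e$eaf)

  ivs <- data.frame(
    variant_id = e$variant_id,
    chrom = e$chrom,
    pos = e$pos,
    beta_exp = beta_exp,
    se_exp = e$se,
    beta_out = beta_out,
    se_out = o$se,
    eaf = eaf,
    pvalue_exp = e$pvalue,
    n_exp = e$n,
    n_out = o$n,
    stringsAsFactors = FALSE
  )
  ivs$r2_exp <- compute_r2(ivs$beta_exp, ivs$eaf, ivs$se_exp, ivs$n_exp)
  ivs$r2_out <- compute_r2(ivs$beta_out, ivs$eaf, ivs$se_out, ivs$n_out)
  ivs$f_stat <- compute_f(ivs$r2_exp, ivs$n_exp)
  rownames(ivs) <- NULL
  counts <- c(n_common = n_common, n_palindromic = n_palindromic,
              n_incompatible = n_incompatible, n_missing_eaf = n_missing_eaf,
              n_harmonized = nrow(ivs))
  if (n_palindromic + n_incompatible + n_missing_eaf > 0) {
    msg("harmonize: %d common, dropped %d palindromic, %d allele-incompatible, %d missing EAF",
        n_common, n_palindromic, n_incompatible, n_missing_eaf)
  }
  structure(ivs, counts = counts, class = c("harmonized_ivs", "data.frame"))
}

.IV_TABLE_COLS <- c("variant_id", "beta_exp", "se_exp", "beta_out", "se_out",
                    "eaf", "r2_exp", "r2_out", "f_stat")

#' Write / read a harmonized instrument table
#'
#' Fixed-column-order TSV round trip for harmonized instruments.
#' @param ivs A `harmonized_ivs` data.frame.
#' @param path Output / input TSV path.
#' @export
write_iv_table <- function(ivs, path) {
  extra <- setdiff(names(ivs), .IV_TABLE_COLS)
  data.table::fwrite(ivs[, c(.IV_TABLE_COLS, extra), drop = FALSE],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_iv_table
#' @export
read_iv_table <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  missing <- setdiff(c("variant_id", "beta_exp", "se_exp", "beta_out", "se_out"),
                     names(df))
  assert_that(length(missing) == 0, "input error: IV table lacks column(s): %s",
              paste(missing, collapse = ", "))
  structure(df, class = c("harmonized_ivs", "data.frame"))
}
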