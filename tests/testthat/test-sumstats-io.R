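test_that("read_sumstats reads well-formed tables and drops invalid rows", {
  tab <- rbind(ss_row("rs1"), ss_row("rs2", beta = -0.2), ss_row("rs3", ea = "T", oa = "C"))
  path <- write_tsv(tab)
  got <- read_sumstats(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$variant_id, c("rs1", "rs2", "rs3"))
  expect_identical(attr(got, "n_dropped"), 0L)

  bad <- rbind(tab, ss_row("rs4", se = 0), ss_row("rs5", eaf = 1.2))
  got2 <- read_sumstats(write_tsv(bad))
  expect_equal(nrow(got2), 3)
  expect_equal(attr(got2, "n_dropped"), 2)

  # alleles are upper-cased
  low <- ss_row("rs1"); low$effect_allele <- "a"; low$other_allele <- "g"
  expect_equal(read_sumstats(write_tsv(low))$effect_allele, "A")
})

test_that("read_sumstats resolves columns through column_map and errors usefully", {
  tab <- ss_row("rs1")
  names(tab)[names(tab) == "beta"] <- "Effect"
  names(tab)[names(tab) == "eaf"] <- "MAF"
  path <- write_tsv(tab)
  got <- read_sumstats(path, column_map = list(beta = "Effect", eaf = "MAF"))
  expect_equal(got$beta, 0.1)
  # frequency column passed through unchanged; orientation is the caller's job
  expect_equal(got$eaf, 0.3)
  expect_error(read_sumstats(path), "required column 'beta'")
  empty <- tempfile(fileext = ".tsv")
  writeLines("variant_id\teffect_allele\tother_allele\tbeta\tse", empty)
  expect_error(read_sumstats(empty), "empty")
})

test_that("read_sumstats accepts gzipped input", {
  path <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(path, "w")
  utils::write.table(ss_row("rs1"), con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  expect_equal(nrow(read_sumstats(path)), 1)
})

test_that("is_palindromic matches the definition", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_equal(is_palindromic(c("A", "T", "C"), c("T", "G", "A")),
               c(TRUE, FALSE, FALSE))
})

test_that("harmonize aligns alleles, drops palindromes, orients beta_exp >= 0", {
  exp <- rbind(ss_row("rs1", ea = "A", oa = "G", beta = 0.1),
               ss_row("rs2", ea = "A", oa = "T", beta = 0.3),   # palindromic
               ss_row("rs3", ea = "C", oa = "T", beta = -0.2),  # negative exposure
               ss_row("rs4", ea = "A", oa = "G", beta = 0.1))   # absent from outcome
  out <- rbind(ss_row("rs1", ea = "G", oa = "A", beta = 0.2, n = 60000),  # swapped
               ss_row("rs2", ea = "A", oa = "T", beta = 0.1, n = 60000),
               ss_row("rs3", ea = "C", oa = "T", beta = 0.05, n = 60000))
  h <- harmonize(exp, out)
  expect_s3_class(h, "harmonized_ivs")
  expect_setequal(h$variant_id, c("rs1", "rs3"))
  # swapped alleles force a sign flip
  expect_equal(h$beta_out[h$variant_id == "rs1"], -0.2)
  # orientation: both betas flipped, eaf complemented
  expect_equal(h$beta_exp[h$variant_id == "rs3"], 0.2)
  expect_equal(h$beta_out[h$variant_id == "rs3"], -0.05)
  expect_equal(h$eaf[h$variant_id == "rs3"], 0.7)
  expect_true(all(h$beta_exp >= 0))
  cnt <- attr(h, "counts")
  expect_equal(unname(cnt["n_common"]), 3)
  expect_equal(unname(cnt["n_palindromic"]), 1)
  expect_equal(unname(cnt["n_harmonized"]), 2)
})

test_that("harmonize rescues strand flips and drops incompatible alleles", {
  exp <- rbind(ss_row("rs1", ea = "A", oa = "G", beta = 0.1),
               ss_row("rs2", ea = "A", oa = "G", beta = 0.1))
  # rs1 reported on the other strand (A/G -> T/C); rs2 alleles irreconcilable
  out <- rbind(ss_row("rs1", ea = "T", oa = "C", beta = 0.15, n = 60000),
               ss_row("rs2", ea = "A", oa = "C", beta = 0.15, n = 60000))
  h <- harmonize(exp, out)
  expect_equal(h$variant_id, "rs1")
  expect_equal(h$beta_out, 0.15)
  expect_equal(unname(attr(h, "counts")["n_incompatible"]), 1)
})

test_that("harmonize errors on duplicates and drops missing exposure EAF", {
  exp <- rbind(ss_row("rs1"), ss_row("rs1"))
  expect_error(harmonize(exp, ss_row("rs1", n = 6e4)), "duplicate")
  exp2 <- rbind(ss_row("rs1"), ss_row("rs2"))
  exp2$eaf[2] <- NA
  h <- harmonize(exp2, rbind(ss_row("rs1", n = 6e4), ss_row("rs2", n = 6e4)))
  expect_equal(h$variant_id, "rs1")
  expect_equal(unname(attr(h, "counts")["n_missing_eaf"]), 1)
})

test_that("harmonize is idempotent and sign-flip is an involution", {
  set.seed(42)
  n <- 20
  pairs <- matrix(c("A", "G", "C", "T", "G", "T", "A", "C"), ncol = 2, byrow = TRUE)
  idx <- sample.int(4, n, replace = TRUE)
  exp <- do.call(rbind, lapply(seq_len(n), function(i) {
    ss_row(sprintf("rs%02d", i), ea = pairs[idx[i], 1], oa = pairs[idx[i], 2],
           beta = rnorm(1, 0, 0.1), se = 0.01, eaf = runif(1, 0.1, 0.9),
           pos = i * 1e5)
  }))
  out <- exp
  out$beta <- rnorm(n, 0, 0.05)
  out$se <- 0.02
  out$n <- 60000
  h1 <- harmonize(exp, out)

  # rebuild both sides from the harmonized output and re-harmonize
  rebuild <- function(h, side) {
    df <- ss_row(h$variant_id, ea = "A", oa = "G")
    df$beta <- if (side == "exp") h$beta_exp else h$beta_out
    df$se <- if (side == "exp") h$se_exp else h$se_out
    df$eaf <- h$eaf
    df$n <- if (side == "exp") h$n_exp else h$n_out
    df$pos <- h$pos
    df
  }
  h2 <- harmonize(rebuild(h1, "exp"), rebuild(h1, "out"))
  expect_equal(h2$beta_exp, h1$beta_exp)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf, h1$eaf)

  # swapping outcome alleles (with sign/eaf flips) reproduces identical beta_out
  out_sw <- out
  tmp <- out_sw$effect_allele
  out_sw$effect_allele <- out_sw$other_allele
  out_sw$other_allele <- tmp
  out_sw$beta <- -out_sw$beta
  out_sw$eaf <- 1 - out_sw$eaf
  h3 <- harmonize(exp, out_sw)
  expect_equal(h3$beta_out, h1$beta_out)

  # counts conserved: common = palindromic + incompatible + missing eaf + kept
  cnt <- attr(h1, "counts")
  expect_equal(unname(cnt["n_common"]),
               unname(cnt["n_palindromic"] + cnt["n_incompatible"] +
                        cnt["n_missing_eaf"] + cnt["n_harmonized"]))
})

test_that("IV table TSV round trip preserves the fixed column order", {
  ivs <- make_ivs(c(0.1, 0.2, 0.3))
  ivs$r2_exp <- compute_r2(ivs$beta_exp, ivs$eaf, ivs$se_exp, 14296)
  ivs$r2_out <- compute_r2(ivs$beta_out, ivs$eaf, ivs$se_out, 60000)
  ivs$f_stat <- compute_f(ivs$r2_exp, 14296)
  path <- tempfile(fileext = ".tsv")
  write_iv_table(ivs, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(header[1:9],
                   c("variant_id", "beta_exp", "se_exp", "beta_out", "se_out",
                     "eaf", "r2_exp", "r2_out", "f_stat"))
  back <- read_iv_table(path)
  expect_equal(back$beta_exp, ivs$beta_exp)
  expect_error(read_iv_table(write_tsv(data.frame(a = 1))), "lacks column")
})
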