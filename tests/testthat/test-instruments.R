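test_that("compute_r2 matches the printed formula and is EAF-invariant", {
  expect_equal(compute_r2(0, 0.3, 0.01, 1000), 0)
  # direct arithmetic: b^2/(b^2 + N SE^2) = 0.01/(0.01 + 1)
  expect_equal(compute_r2(0.1, 0.3, 0.01, 10000), 0.01 / 1.01, tolerance = 1e-12)
  r2s <- vapply(c(0.1, 0.3, 0.49), function(p) compute_r2(0.1, p, 0.01, 10000),
                numeric(1))
  expect_true(max(r2s) - min(r2s) < 1e-14)
  expect_error(compute_r2(Inf, 0.3, 0.01, 100), "non-finite")
  expect_error(compute_r2(0.1, 1.2, 0.01, 100), "eaf")
})

test_that("compute_f matches the printed formula and is monotone in r2", {
  expect_equal(compute_f(0, 100), 0)
  expect_equal(compute_f(0.5, 4), 2)
  grid <- seq(0, 0.9, by = 0.05)
  fs <- compute_f(grid, 5000)
  expect_true(all(diff(fs) > 0))
  expect_error(compute_f(1, 100), "r2")
})

test_that("F column is bit-identical to recomputation from R2", {
  sim <- simulate_pair(sim_config(n_snps = 20, theta = 0.1, seed = 99))
  ivs <- harmonize(sim$exposure, sim$outcome)
  expect_identical(ivs$f_stat, compute_f(compute_r2(ivs$beta_exp, ivs$eaf,
                                                    ivs$se_exp, ivs$n_exp),
                                         ivs$n_exp))
})

test_that("ld_clump basics: single candidate, LD competition, windows", {
  cfg <- clump_config()
  one <- data.frame(variant_id = "v1", chrom = "1", pos = 1e6L, pvalue = 1e-8)
  expect_equal(ld_clump(one, NULL, cfg), "v1")

  two <- data.frame(variant_id = c("v1", "v2"), chrom = "1",
                    pos = c(1e6L, 11e5L), pvalue = c(1e-10, 1e-8))
  panel <- ld_panel(c("v1", "v2"), matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(ld_clump(two, panel, cfg), "v1")
  # beyond the 500 kb window the same pair is independent
  two$pos[2] <- 2e6L
  expect_equal(ld_clump(two, panel, cfg), c("v1", "v2"))
  # cross-chromosome pairs are independent regardless of the panel
  two$pos[2] <- 11e5L; two$chrom <- c("1", "2")
  expect_equal(ld_clump(two, panel, cfg), c("v1", "v2"))
  # below the p threshold nothing enters
  none <- data.frame(variant_id = "v1", chrom = "1", pos = 1e6L, pvalue = 1e-3)
  expect_equal(ld_clump(none, panel, cfg), character(0))
})

test_that("ld_clump equals the exhaustive maximal-independent-set oracle", {
  cfg <- clump_config(window_kb = 500, r2_threshold = 0.1, p_threshold = 1e-4)
  for (seed in 1:40) {
    n <- sample(2:12, 1)
    inst <- random_clump_instance(n, seed)
    got <- ld_clump(inst$candidates, inst$panel, cfg)
    want <- oracle_clump(inst$candidates, inst$panel, cfg)
    expect_setequal(got, want)
  }
})

test_that("on an LD-free panel ld_clump returns exactly the p-filtered set", {
  set.seed(7)
  n <- 15
  ids <- sprintf("v%02d", seq_len(n))
  cand <- data.frame(variant_id = ids, chrom = "1",
                     pos = as.integer(seq_len(n) * 1e4),
                     pvalue = 10^-runif(n, 4, 10))
  panel <- ld_panel(ids, diag(1, n))
  cfg <- clump_config(p_threshold = 1e-6)
  expect_setequal(ld_clump(cand, panel, cfg),
                  cand$variant_id[cand$pvalue < 1e-6])
  # post-hoc invariant: accepted sets are pairwise below threshold in windows
  inst <- random_clump_instance(10, 123)
  kept <- ld_clump(inst$candidates, inst$panel, clump_config(p_threshold = 1e-2))
  pos <- inst$candidates$pos[match(kept, inst$candidates$variant_id)]
  chr <- inst$candidates$chrom[match(kept, inst$candidates$variant_id)]
  for (i in seq_along(kept)) for (j in seq_along(kept)) {
    if (i < j && chr[i] == chr[j] && abs(pos[i] - pos[j]) <= 5e5) {
      expect_lt(inst$panel$r2[kept[i], kept[j]], 0.1)
    }
  }
})

test_that("steiger_filter keeps forward, removes reverse instruments", {
  ivs <- make_ivs(c(0.1, 0.2))
  ivs$r2_exp <- c(0.05, 0.0001)
  ivs$r2_out <- c(0.0001, 0.05)
  st <- steiger_filter(ivs, n_exp = 14296, n_out = 60000)
  expect_equal(st$kept$variant_id, "iv01")
  expect_equal(st$removed, "iv02")
})

test_that("steiger_filter removes most instruments under reverse causation", {
  removed_frac <- vapply(1:20, function(s) {
    sim <- simulate_pair(sim_config(n_snps = 30, theta = 0.3, reverse = TRUE,
                                    seed = 1000 + s))
    ivs <- harmonize(sim$exposure, sim$outcome)
    st <- steiger_filter(ivs, 14296, 85716)
    length(st$removed) / nrow(ivs)
  }, numeric(1))
  expect_gt(mean(removed_frac), 0.8)
})

test_that("select_instruments applies the full filter cascade", {
  sim <- simulate_pair(sim_config(n_snps = 10, theta = 0.2, gamma_min = 0.15,
                                  seed = 5))
  ivs <- select_instruments(sim$exposure, sim$outcome, sim$panel, clump_config())
  # 10 independent strong variants all survive
  expect_equal(nrow(ivs), 10)
  expect_true(all(ivs$f_stat >= 10))
  log <- attr(ivs, "selection_log")
  expect_equal(log$n_input, 10)

  # no variant reaches significance -> empty with reason
  weak <- sim$exposure
  weak$beta <- weak$beta / 50
  weak$pvalue <- 2 * pnorm(-abs(weak$beta / weak$se))
  empty <- select_instruments(weak, sim$outcome, sim$panel, clump_config())
  expect_equal(nrow(empty), 0)
  expect_match(attr(empty, "reason"), "no significant")

  # high-EAF variant fails the minor-allele-frequency filter
  rare <- sim$exposure
  rare$eaf[1] <- 0.97
  ivs2 <- select_instruments(rare, sim$outcome, sim$panel, clump_config())
  expect_false(sim$exposure$variant_id[1] %in% ivs2$variant_id)
  expect_equal(attr(ivs2, "selection_log")$n_maf_fail, 1)
})

test_that("select_instruments optional outlier pass removes a planted outlier", {
  sim <- simulate_pair(sim_config(n_snps = 20, theta = 0.2, outlier_frac = 0.05,
                                  outlier_shift = 10, gamma_min = 0.2, seed = 21))
  with_pass <- select_instruments(sim$exposure, sim$outcome, sim$panel,
                                  clump_config(), presso_n_sim = 1000, seed = 3)
  expect_false(any(sim$truth$outlier_ids %in% with_pass$variant_id))
  without <- select_instruments(sim$exposure, sim$outcome, sim$panel, clump_config())
  expect_true(all(sim$truth$outlier_ids %in% without$variant_id))
})

test_that("LD panel constructors validate and read both TSV dialects", {
  expect_error(ld_panel(c("a", "b"), matrix(c(1, 0.5, 0.4, 1), 2)), "symmetric")
  expect_error(ld_panel(c("a", "b"), matrix(c(1, 0.5, 0.5, 2), 2)), "diagonal|\\[0,1\\]")
  m <- matrix(c(1, 0.25, 0.25, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- ld_panel(c("a", "b"), m)
  sq <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(id = c("a", "b"), a = m[, 1], b = m[, 2]),
                     sq, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_ld_panel(sq)$r2, p$r2)
  long <- write_tsv(data.frame(id1 = "a", id2 = "b", r2 = 0.25))
  expect_equal(read_ld_panel(long)$r2, p$r2)
  # dosage helper: squared Pearson correlation
  set.seed(1)
  d <- matrix(rbinom(300, 2, 0.3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(ld_from_dosage(d)$r2, stats::cor(d)^2, ignore_attr = TRUE)
})
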