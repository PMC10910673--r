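# mrscreen

Two-sample Mendelian randomization (MR) screening of GWAS summary
statistics, built for the setting where hundreds of quantitative exposures
(typically plasma metabolites, in SD units) are screened against a panel of
binary disease outcomes (typically cancers, on the log-odds scale) using
nothing but publicly shared association tables.

The package is aimed at genetic epidemiologists who want every stage of the
screen — instrument selection, estimation, diagnostics, and the final
judgement call — as reusable, deterministic, *testable* code, plus a
synthetic summary-statistic generator so the whole machine can be exercised
and calibrated at desk scale without touching any consortium data.

## What it computes

For each variant `j` with exposure association `(β̂_Xj, σ_Xj)` and outcome
association `(β̂_Yj, σ_Yj)` after harmonization:

- **Instrument strength.** Variance explained
  `R²_j = (2β̂²·EAF·(1−EAF)) / (2β̂²·EAF·(1−EAF) + 2N·EAF·(1−EAF)·σ²)` and
  `F_j = R²_j (N−2)/(1−R²_j)`; instruments with `F < 10` are discarded.
- **Selection.** MAF > 0.05, non-palindromic alleles, exposure significance
  (`P < 1e−6` primary; `P < 5e−8` stringent), greedy LD clumping (pairwise
  `r² < 0.1` in 500 kb; `r² < 0.001` in 1000 kb stringent), and the Steiger
  directionality test (`R²_X > R²_Y`, Fisher-z comparison).
- **Estimators.** Wald ratios `β̂_Yj/β̂_Xj`; inverse-variance weighted (IVW)
  pooling with fixed or multiplicative random effects; the weighted median
  (consistent with up to half the weight on invalid instruments); Egger
  regression (slope = pleiotropy-adjusted effect, intercept = average
  directional pleiotropy).
- **Diagnostics.** Cochran's Q, leave-one-out dominance, and a seeded
  simulation-based residual-sum-of-squares framework for global pleiotropy,
  per-instrument outliers, and estimate distortion.
- **Multivariable MR** (direct effects conditional on co-screened exposures,
  with a conditional instrument-strength statistic), **approximate-Bayes-factor
  colocalization** (posterior PP0–PP4 over the five single-causal-variant
  hypotheses at each instrument's locus), and **asymptotic power** for a
  binary outcome at case fraction `k`.
- **The confidence ledger.** An association is *confident* iff it passes a
  per-cancer Bonferroni-corrected IVW test with secondary-method support,
  is direction-consistent across all estimators, uses only `F > 10`
  instruments, and shows no heterogeneity, no pleiotropy (Egger intercept
  and global test), and leave-one-out stability.

## Worked example

```r
library(mrscreen)

presets <- scenario_presets(7)          # named, documented simulation worlds
sim <- simulate_pair(presets$causal)    # theta = 0.2 log-odds/SD, 50 IVs

ivs <- select_instruments(sim$exposure, sim$outcome, sim$panel, clump_config())
res <- mr_all_methods(ivs, seed = 7)
res$ivw
#> MR ivw estimate (50 IVs)
#>   OR 1.214 (95% CI 1.202-1.226), beta 0.1939 (SE 0.0051), p = 0
#>   Cochran Q 57.88 on 49 df, p = 0.18
res$egger
#> MR egger estimate (50 IVs)
#>   OR 1.208 (95% CI 1.184-1.232), beta 0.1887 (SE 0.0099), p = 5.58e-24
#>   Egger intercept 0.0022, p = 0.539
#>   Cochran Q 57.42 on 48 df, p = 0.166

run_presso(ivs, n_sim = 5000, seed = 7)
#> Pleiotropy residual-sum-of-squares test (n_sim = 5000, seed = 7)
#>   RSS = 59.584, global p = 0.2749
#>   no outliers detected; raw estimate stands

sc <- screen_pair(sim$exposure, sim$outcome, sim$panel, seed = 7,
                  bonferroni_m = 579, n_sim = 2000)
sc$ledger[, c("confident", "failed_criteria")]
#>   confident failed_criteria
#> 1      TRUE
```

The generating truth was `theta = 0.2` per SD; IVW recovers `0.194 ± 0.005`,
the weighted median `0.191`, Egger `0.189` with a null intercept, no outliers
are flagged, and the six-criterion ledger admits the association. Swap in the
`directional_pleiotropy` or `reverse_causal` preset and the ledger (or the
Steiger filter) rejects it, with the reason recorded.

A command-line front end covers the same stages
(`simulate | select | mr | presso | mvmr | coloc | screen | report`):

```sh
Rscript -e 'mrscreen::mrscreen_main()' simulate --preset causal --seed 7 --out-dir sim/
Rscript -e 'mrscreen::mrscreen_main()' select --exposure sim/exposure.tsv \
    --outcome sim/outcome.tsv --out-dir out/
Rscript -e 'mrscreen::mrscreen_main()' mr --ivs out/ivs.tsv --seed 7 --out-dir out/
```

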