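---
title: "Models, assumptions and design choices in mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and design choices in mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

# The screening problem

Two-sample Mendelian randomization treats genetic variants as natural
instruments: a variant that changes the plasma level of a metabolite, and
can plausibly affect disease risk *only* through that metabolite, converts
two association tables — variant→exposure from one cohort, variant→outcome
from another — into an estimate of the causal effect of the exposure on the
outcome. At screening scale (hundreds of metabolites × several cancers) the
scientific risk is not the arithmetic but the validity triage: weak
instruments, pleiotropic variants, heterogeneity, reverse causation, and
simple multiple testing. This package implements the full triage as code.

All exposure effects are per SD of the quantitative trait; all outcome
effects are log-odds. The causal estimand `theta` is therefore log-odds of
disease per SD of exposure, reported as an odds ratio `exp(theta)`.

# Instrument selection

The cascade, in order, with its tunable thresholds (`clump_config()`):

| step | default (primary) | stringent profile | why |
|---|---|---|---|
| MAF filter | exposure-study minor-allele frequency > 0.05 | same | rare variants have unstable frequencies and effects across panels |
| palindrome exclusion | drop A/T and C/G pairs | same | strand cannot be resolved from alleles alone |
| exposure significance | P < 1e-6 | P < 5e-8 | instrument relevance |
| LD clumping | pairwise r² < 0.1 within 500 kb | r² < 0.001 within 1000 kb | approximate independence for IVW weighting |
| instrument strength | F ≥ 10 | same | weak-instrument bias control |
| Steiger direction | R²(exposure) > R²(outcome), one-sided Fisher-z p < 0.05 | same | removes variants whose primary effect is on the outcome |
| minimum set size | ≥ 3 instruments | same | Egger and the weighted median need ≥ 3 |

Notes on the less obvious choices:

- **MAF uses the exposure-study EAF**, folded to a minor-allele frequency.
  A reference-panel frequency check would need the panel itself; using the
  study EAF is a documented approximation.
- **Clumping is greedy by ascending p-value** with ties broken by
  (chromosome, position, id) for cross-platform determinism. A candidate is
  accepted iff its LD with every previously accepted variant on the same
  chromosome within the window is below the threshold. The test suite
  proves the greedy result equals the lexicographically-first maximal
  independent set of the conflict graph by exhaustive enumeration on all
  instances of ≤ 12 candidates.
- **LD comes from a user-supplied panel** (square or long TSV, or squared
  Pearson correlation of a dosage matrix). Reference-panel retrieval is out
  of scope; synthetic runs emit exact panels.
- **The Steiger test** is the independent-samples comparison of
  Fisher-transformed correlations `atanh(sqrt(R²))` with variances
  `1/(N−3)`: the exposure and outcome GWAS are disjoint cohorts, so the
  paired form does not apply. For a binary outcome the observed-scale R² is
  used; this makes the filter conservative in favour of the forward
  direction when case fractions are moderate (the outcome R² is deflated by
  `k(1−k)`), which is the safe direction for a screen.
- **One optional outlier-removal pass** (the simulation-based per-instrument
  test below) can run after selection and before final estimation; the
  orchestration layer enables it, `select_instruments()` alone does not.
  It is a single pass, not iterated to convergence.

`R²` is computed from the printed-formula form
`(2β²·EAF(1−EAF)) / (2β²·EAF(1−EAF) + 2N·EAF(1−EAF)·SE²)`; the EAF factors
cancel algebraically (the tests verify numeric invariance to EAF), but the
full expression is evaluated as stated so the code matches the field's
reporting convention. `F = R²(N−2)/(1−R²)`, and the written instrument
table reproduces `compute_f(compute_r2(...))` bit-identically.

# Estimators

With Wald ratios `r_j = β̂_Yj/β̂_Xj` and first-order weights
`w_j = β̂²_Xj/σ²_Yj`:

- **IVW**: `θ̂ = Σ w_j r_j / Σ w_j`. Default standard errors are
  *multiplicative random effects*: the fixed-effect SE inflated by
  `max(1, sqrt(Q/(k−1)))`. The point estimate is identical under both
  conventions (tested); only the CI widens under heterogeneity. The
  `max(1,·)` floor never rewards under-dispersion.
- **Weighted median**: order the ratios, accumulate normalized weights,
  interpolate linearly at cumulative weight 0.5. The SE is a seeded
  parametric bootstrap (`n_boot = 1000` by default) resampling each ratio
  from `N(r_j, se_j)`; it is reproducible bit-for-bit given `(n_boot,
  seed)`.
- **Egger regression**: weighted least squares of `β̂_Y` on `β̂_X` *with*
  intercept, weights `1/σ²_Y`, instruments oriented so `β̂_X ≥ 0` (the
  harmonization convention — the intercept is meaningless without a fixed
  orientation). Slope = causal effect under InSIDE; intercept = average
  directional pleiotropy. SEs carry the same `max(1,·)` dispersion floor;
  p-values and CIs use the t distribution on `k−2` df (the normal
  alternative is anti-conservative at screening-scale instrument counts).
- **Wald ratio** (single instrument): first-order delta-method SE
  `σ_Y/|β_X|`, consistent with the IVW weights. The second-order form adds
  `β²_Y σ²_X / β⁴_X`; the tests check the first-order SE is within 10% of
  it whenever `σ_X/β_X < 0.1` and the outcome z-score is moderate — the
  regime the F ≥ 10 filter enforces.

**p-values** are normal-based for Wald/IVW/weighted-median and t-based for
Egger slope and intercept.

# The outlier framework

The global, per-instrument and distortion tests follow the
residual-sum-of-squares logic: each instrument's residual is taken against
the *fixed-effect* IVW fit excluding it; the observed weighted RSS is
compared against `n_sim` parametric replicates drawing
`β*_Xj ~ N(β̂_Xj, σ_Xj)` and `β*_Yj ~ N(fitted_j, σ_Yj)`. All p-values use
the add-one estimator `(1 + #exceedances)/(n_sim + 1)`, so the attainable
floor `1/(n_sim+1)` is explicit and no simulation p is ever zero.
Per-instrument p-values are Bonferroni-multiplied by the instrument count;
flagged instruments with corrected p < 0.05 are outliers. The distortion
coefficient is `100·(θ̂_raw − θ̂_corrected)/|θ̂_corrected|`, with a null built
from random outlier-index sets of the same size. Defaults: `n_sim = 5000`
for analyses, 1000 (the enforced floor) in tests. When nothing is flagged
the raw IVW estimate stands and no corrected estimate is reported.

# Multivariable MR

Direct effects come from weighted least squares of the outcome effects on
the instrument-by-exposure effect matrix without intercept, weights
`1/σ²_Y`, SEs inflated by `max(1, sqrt(Q/(k−p)))`. Instruments are the
union over the co-screened exposures, deduplicated by variant; an exposure
effect missing for a union instrument is **zero-imputed with a logged
count** — a documented assumption, defensible because a variant selected
for one metabolite and absent from another's association table is almost
always a non-association rather than missing data, but an assumption
nonetheless. Rank deficiency raises an error naming the dependent columns.

The conditional instrument-strength statistic regresses each exposure's
instrument effects on the other exposures' (ordinary least squares, no
intercept) and summarizes the residual signal as
`cF = max(0, mean(resid²/σ²_X) − 1)`. The `−1` subtracts the pure-noise
expectation, so perfectly collinear exposures give `cF → 0` while mutually
orthogonal strong instruments give `cF` close to the mean univariable F
(up to O(1)). This is a diagnostic heuristic, not the full
heteroscedasticity-robust conditional-F machinery.

# Colocalization

Per instrument locus (±500 kb by default, mirroring the clumping window —
"locus" has no sharper definition in the screening context), the five
single-causal-variant hypotheses are weighed by Wakefield approximate Bayes
factors `log ABF = ½log(1−r) + ½rz²` with `r = W/(V+W)`; the tests verify
this closed form against numeric quadrature of the normal-prior marginal
likelihood to 1e-6. Prior effect SDs default to 0.15 (quantitative trait)
and 0.2 (binary, log-odds); configuration priors default to
`p1 = p2 = 1e-4`, `p12 = 1e-5`. Sums over configurations use log-sum-exp
throughout; H3 (two distinct causal variants) is computed as the
complement `Σ_i Σ_j − Σ_{i=j}` on the log scale. A locus "colocalizes" at
`PP4 > 0.5` — deliberately the *moderate* threshold used in the screening
literature rather than the stricter 0.8, and a config value.

# Power

For a binary outcome at case fraction `k`, hypothesized odds ratio `OR`,
total instrument `R²` and outcome GWAS size `N`, the log-odds effect is
attenuated to the observed-risk scale as
`b = k(1−k)(OR−1)/(1 + k(OR−1))` — the exact risk difference implied by a
one-unit log-odds shift at baseline `k` — giving non-centrality
`NCP = N·R²·b²/(k(1−k))` and two-sided power
`Φ(−z_{1−α/2} + √NCP) + Φ(−z_{1−α/2} − √NCP)`. The commonly circulated
shorthand omits the `(1−k)` factor in `b`; the exact form is used because
only it matches Monte-Carlo power across case fractions, which is the
acceptance standard here (within 0.03 on a 12-point grid, with the
Monte-Carlo arm using fixed-effect IVW — the asymptotic model being
tested — and instrument strength mirroring real metabolite instruments:
seven instruments, ~9.5% summed R²).

# The confidence ledger

A screened association is **confident** iff all of:

1. IVW p passes the per-outcome Bonferroni correction (`m` = number of
   exposures screened for that outcome; logged and configurable, e.g. 579)
   *and* at least one other estimator has p < 0.05;
2. all four estimators agree in direction;
3. every instrument has F > 10;
4. Cochran's Q p > 0.05;
5. Egger intercept p > 0.05 *and* global outlier-test p > 0.05;
6. no leave-one-out exclusion flips the effect sign or moves the 95% CI
   across OR = 1 (the operationalization of "not driven by a single IV").

The Bonferroni boundary is inclusive (corrected p exactly 0.05 passes).
Because criteria 4–6 each consume ~5% of perfectly valid associations, the
conjunction admits a truly causal synthetic association about 85% of the
time — the designed cost of a stringent screen, and the reason the
acceptance tests assert preset behaviour over replicates rather than on a
single dataset.

Reverse MR (outcome as exposure, stringent selection profile) runs
alongside the ledger and raises a flag at IVW p < 0.05; an instrument set
emptied by the significance or Steiger filters is reported as
`insufficient_instruments` with the recorded reason.

# The synthetic-statistic generator

`simulate_pair()` draws, per variant: EAF ~ Uniform(0.10, 0.50);
variant→exposure effect `γ` from a floor-plus-half-normal
`sign(v)(γ_min + |v|)`, `v ~ N(mean, sd)` (defaults `γ_min = 0.08`,
`sd = 0.2`) — the floor guarantees instrument significance, and the
half-normal tail spreads instrument strength the way strong metabolite
*cis* effects spread in real data; exposure noise at
`σ_X = 1/sqrt(2·N_X·EAF(1−EAF))` (N_X defaults to 14,296) and case-control
outcome noise at `σ_Y = 1/sqrt(N_Y·k(1−k)·2·EAF(1−EAF))` (defaults
N_Y = 85,716, k = 0.341). The outcome effect is `θγ + α + shift`:

- **Pleiotropy** `α` is drawn on the *oriented* (exposure-increasing
  allele) scale and applied with the instrument's sign. This matters:
  directional pleiotropy applied in raw allele space becomes balanced after
  harmonization orients `β_X ≥ 0`, and the Egger intercept would correctly
  center at zero — the generator would not be simulating what "directional"
  means to the estimator.
- **Outlier shifts** follow the same orientation convention (displaced Wald
  ratios share a direction), in units of the variant's outcome SE.
- **Reverse mode** flips the arrow: variants act on the outcome, the
  exposure inherits `θ` times the variant effect.

What a green test does **not** establish: the generator draws marginal
statistics independently even when an LD panel with blocks is emitted (LD
shapes clumping, not the sampling correlation of effect estimates); binary
outcome effects are generated directly on the log-odds scale with the
standard SE approximation rather than by individual-level logistic
sampling; EAFs are uniform rather than ascertainment-shaped; and no
genome-wide negative background is simulated. Calibration and recovery
results therefore validate the estimators and the triage logic, not the
idiosyncrasies of any particular consortium dataset.

`scenario_presets()` freezes eight named worlds (null, causal,
balanced/directional pleiotropy, outliers, weak instruments, reverse
causal, two-cohort replication) with derived per-preset seeds. The causal
preset widens the effect spread (`sd = 0.3`): Egger's slope attenuates as
instrument strength homogenizes (the familiar instrument-strength
heterogeneity requirement), and the estimator-recovery testbed is
deliberately placed in the regime where Egger is well identified. Even so
a small exposure-measurement-error attenuation (≈1% of θ at these cohort
sizes) is visible in high-replicate runs; it vanishes as N_X grows, and the
recovery criterion's replicate count keeps it inside three Monte-Carlo SEs
without hiding that it exists.

`simulate_region()` builds colocalization loci: one causal variant per
trait (shared or not), z-scores decaying along an exponential LD curve,
with AR(1)-correlated noise matching the same decay — independent noise
would make neighbouring z-scores mutually inconsistent and spuriously
favour the two-distinct-variants hypothesis.

# Numerical and degenerate-input policy

- Simulation p-values use add-one estimators; log-domain sums use
  log-sum-exp / log-diff-exp with an explicit `−Inf` guard for H3 at
  single-variant loci.
- Wald ratios at `β_X = 0` raise an undefined-ratio error (upstream
  orientation makes `β_X > 0` for every selected instrument).
- Ties in clumping are broken deterministically; identical runs with
  identical seeds produce byte-identical outputs (tested).
- Invalid summary-statistic rows are dropped with logged counts, never
  silently repaired; duplicate variant ids are an error, not a dedup.
- Random-number state is saved and restored around every seeded routine,
  so library calls do not perturb a caller's RNG stream.

# Known limitations

- No correlated-instrument IVW; clumping to near-independence is assumed
  sufficient, as in the screening practice this package mirrors.
- No mode-based or penalized estimators, no multivariable Egger, no
  SuSiE-style multi-causal colocalization, no LD-score genetic correlation
  (requires genome-wide statistics and an LD-score reference).
- The Steiger observed-scale R² comparison is conservative for binary
  outcomes, as discussed above.
- Zero-imputation of missing exposure effects in multivariable MR is an
  assumption, flagged and counted at run time.
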