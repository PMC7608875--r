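---
title: "Measuring and decomposing wealth inequality in child severe wasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing wealth inequality in child severe wasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Severe wasting — a weight-for-height z-score (WHZ) below −3 SD of a
growth-standard median — is the most dangerous form of acute
undernutrition in children under five. In household surveys from low-
and middle-income countries its burden is unevenly distributed between
children from poor and non-poor households. Two questions follow:

1. **How large is the inequality?** Per country, the difference in
   severe-wasting prevalence between the poor and non-poor groups,
   expressed as a risk difference (RD) per 1000 children, pooled across
   countries by random-effects meta-analysis.
2. **Why does it exist?** A Blinder–Oaxaca decomposition splits the
   prevalence gap into a part *explained* by differences in measurable
   characteristics (covariate levels) and an *unexplained* part
   attributable to differences in the returns to those characteristics.

`swdecomp` implements both stages, together with the variable
construction they need (asset-based wealth index, neighbourhood
disadvantage index, LMS z-scores) and a synthetic survey generator with
analytically known ground truth for validation.

## Variable construction

**Wealth.** Household surveys in this setting carry no income data; the
standard proxy is the first principal component of household asset
indicators. `compute_wealth_index()` extracts that component from the
*weighted correlation matrix* (so the score is invariant to rescaling
any indicator), orients it so that more assets score higher
(majority-positive loadings; ties broken toward a positive loading on
the first column), and cuts weight-balanced quintiles at the weighted
20/40/60/80 percentiles. Households with identical scores share the
lower quintile, which makes the assignment deterministic. The analysis
dichotomy is fixed by convention: *poor* = poorest + poorer quintiles,
*non-poor* = middle + richer + richest.

**Neighbourhood disadvantage.** Clusters (survey PSUs) are summarized
by four weighted proportions — respondents with no education,
unemployed, rural, below the poverty line — and scored on their first
principal component, oriented so that higher = more disadvantaged, with
weighted quintiles labelled "1 (highest SES)" to "5 (lowest SES)".
Whether "below the poverty line" uses the package's own poor/non-poor
dichotomy is a configuration choice (`indicators` argument); the
default maps it to the wealth dichotomy, the only poverty measure the
data carry.

**Outcome.** `whz_zscore()` evaluates the LMS transformation
`z = ((w/M)^L − 1)/(L·S)` (or `log(w/M)/S` when `L = 0`), with linear
interpolation of L, M, S between reference grid rows. Beyond |z| > 3
the restricted (linear-tail) adjustment is applied: the tail is
linearized in weight using the reference's SD2/SD3 spacings, the
standard practice with growth references. Records with |z| > 5 are
flagged implausible and excluded from denominators; severe wasting is
`z < −3` (strict) among plausible records. Both the cutoff and the
plausibility bound are arguments, because published analyses rarely
state their exclusion rules. The packaged reference table
(`lms_reference_synthetic.csv`) is a smooth synthetic surface on a
coarse 45–120 cm grid intended for tests and examples only; real
analyses should supply a full growth-standard table in the same CSV
format, or precomputed WHZ (`outcome_mode = "whz"`).

## Inequality metrics

Prevalences are survey-weighted percentages; the risk difference is
`(prev_poor − prev_nonpoor) × 10` per 1000 children, positive =
pro-poor inequality (the adverse outcome concentrates among the poor).
`rd_inference()` attaches a variance from a cluster-robust Taylor
linearization of the two weighted ratio estimators (PSU-level totals,
with-replacement approximation); a plain binomial variance is available
for comparison because published forest plots rarely state which was
used. Per-country RDs are pooled with the DerSimonian–Laird
random-effects estimator (via `metafor`), giving the overall RD
irrespective of country of residence, with the moment estimate of the
between-country variance τ².

Odds-ratio homogeneity across strata uses the Breslow–Day statistic
with Tarone's correction. Strata default to clusters within country;
strata containing a zero margin receive a 0.5 continuity correction
(prevalences themselves are never corrected).

Countries are classified into four quadrants by prevalence level
(low/high) × inequality direction (pro-poor / pro-non-poor). The
default prevalence threshold is the *mean* country prevalence, each
country counting once: country prevalence distributions in this setting
are strongly right-skewed, and the mean separates the handful of
high-burden countries from the long low-prevalence tail, whereas a
median splits the tail itself. The threshold is configurable.

## The decomposition

Let A = poor, B = non-poor, and `gap = Ȳ_A − Ȳ_B` the difference in
weighted mean outcomes. With group-specific linear models
`Y_g = X_g' β_g + ε`, the threefold decomposition from the viewpoint of
group B is

    gap = (X̄_A − X̄_B)' β_B        (E, endowments)
        + X̄_B' (β_A − β_B)        (C, coefficients)
        + (X̄_A − X̄_B)'(β_A − β_B) (I, interaction)

The twofold decomposition uses a nondiscriminatory reference vector β*:

    gap = (X̄_A − X̄_B)' β*                                    (Q, explained)
        + X̄_A'(β_A − β*) + X̄_B'(β* − β_B)                    (U, unexplained)

with β* chosen as β_B (default), β_A, or the coefficients of a pooled
fit over both groups. The pooled fit includes a group-membership
indicator by default (omitting it pushes part of the group difference
into the covariate coefficients and inflates U; the option exists for
comparison).

**Binary outcome.** Severe wasting is binary, so the group models are
weighted maximum-likelihood logistic regressions and the decomposition
is carried out on the probability scale through counterfactual mean
predictions:

* `E = P̄(X_A, β_B) − P̄(X_B, β_B)`
* `C = P̄(X_B, β_A) − P̄(X_B, β_B)`
* `I = gap − E − C`, and analogously `Q = P̄(X_A, β*) − P̄(X_B, β*)`,
  `U = gap − Q`,

where `P̄(X, β)` is the weighted mean of record-level predicted
probabilities (`scheme = "population"`, the default) or the logistic
function applied to the mean covariate vector (`scheme = "at_means"`).
Defining I and U as the closing terms makes the additivity identities
`E + C + I = gap` and `Q + U = gap` exact by construction on every
input, and makes the twofold split regroup the threefold exactly:
reference B gives `(Q, U) = (E, C + I)`, reference A gives
`(E + I, C)`. In the at-the-means scheme the gap itself is evaluated
at the means (`F(X̄_A'β_A) − F(X̄_B'β_B)`) so that components and gap
share one definition; the two gaps differ only by a Jensen term, and
for converged ML fits with an intercept the population-scheme gap
equals the raw weighted prevalence gap (verifiable with
`nonlinear_gap()`).

**Per-covariate detail.** Under the identity link the element-wise
products are exact. Under the logit link the aggregate components are
allocated across covariates by Yun's weights — the normalized
at-the-means linear terms, e.g. `w_k = Δx̄_k β*_k / Σ_j Δx̄_j β*_j`
for the explained part. If the normalizing sum is zero while the
aggregate is not, the weights are undefined and the package raises an
error rather than reporting arbitrary shares. Categorical covariates
are expanded with deviation (sum-to-zero) contrasts by default, which
makes term-level detail invariant to the choice of omitted category;
conventional dummy coding is available and warns, because its detail
depends on the omitted base.

**Uncertainty.** Variances come from a cluster bootstrap: PSUs are
resampled with replacement (within country when a country column is
supplied), both group models are refitted and the decomposition is
recomputed per replicate. Standard errors are replicate SDs and
intervals are percentile intervals. Replicates with failed fits (e.g. a
resample with no events in a group) are dropped and counted; more than
20% failures aborts the run. The resampling operates on a design matrix
built once from the full data, so factor levels are fixed across
replicates.

## The synthetic generator and its ground truth

`sim_config()`/`generate_population()` emulate the features of
multi-country survey microdata that the analysis relies on:

* hierarchy: countries → clusters (Poisson-sized) → children;
* relative sampling weights, lognormal, normalized to mean 1 within
  country (as survey weights are relative);
* a standard-normal latent household wealth score that drives *both*
  binary asset ownership (monotone logistic item curves) *and* the
  poor/non-poor label (below/above the country's poor-fraction
  quantile), reproducing the confounding structure that makes the
  asset index meaningful;
* categorical covariates with group-specific distributions;
* a binary outcome drawn from group-specific logistic models, with an
  optional cluster-level random intercept (default off, because the
  decomposition itself is single-level).

Defaults are fixed study conditions, chosen once: the covariate mix
(maternal education, media access, residence, child age) uses
group-specific probabilities derived from a pooled LMIC survey profile
(poor households have markedly less education, media access and urban
residence); a poor fraction of 45.6%; and coefficient vectors
calibrated analytically so the default group prevalences are 5.3%
(poor) and 4.2% (non-poor) — the pooled levels typical of this
setting. `true_decomposition()` computes, with no sampling, exact
group prevalences and RD by enumerating the joint categorical
covariate distribution, and the decomposition components in both
evaluation schemes ("at_means" analytically at the mean vectors,
"population" by exact enumeration), so estimator and truth always
share a definition.

What the generator does *not* emulate: multi-stage selection
probabilities, non-response or calibration weighting, real geography,
within-household correlation beyond the shared wealth label, and
missing data. Passing the recovery suites therefore demonstrates
statistical correctness of the estimators under the assumed sampling
model, not robustness to the messiness of real survey files.

## Numerical choices

* Logistic fits use `stats::glm.fit` (quasibinomial family to accept
  non-integer weights) with convergence tolerance 1e−12, so the
  score-equation identity between fitted and observed weighted means
  holds to ~1e−9 and the probability-scale gap matches the raw
  prevalence gap to the same order.
* Rank deficiency is detected by QR before fitting and reported with
  the aliased column names; complete separation is reported when the
  fit fails to converge or linear predictors exceed ±30.
* Closure residuals (the difference between the observed gap and the
  sum of directly computed components, of order machine epsilon for
  WLS and fit tolerance for ML) are assigned to the intercept row of
  the detail table, so detail always sums exactly to its aggregate.
* Weighted quintile cuts use lower-boundary weighted quantiles; ties
  share the lower quintile.
* Wealth-index sign ties (exactly balanced loadings) resolve toward a
  positive loading on the first asset column.

## Problem sizes used in the validation suite

The packaged tests exercise the generator at up to 100,000 children
per wealth group with 50-replicate cluster bootstraps across 20 seeds
for ground-truth recovery, 500-replicate null simulations for the
calibration of the significance flag and of the homogeneity test, 1000
random instances for the algebraic identities, and 100 small datasets
against a brute-force oracle for the identity-link components. These
sizes give Monte-Carlo error comfortably below the tolerances asserted
and run in minutes on a single CPU.

## Known limitations

* The decomposition is associational: components quantify contributions
  of covariate distributions and returns, not causal effects.
* Yun's weights are a first-order allocation; with strong
  nonlinearities the detail (not the aggregates) depends on this
  choice, and alternative detailed-decomposition schemes can give
  different per-covariate shares.
* The Breslow–Day test needs reasonably filled strata; with
  cluster-level strata and rare outcomes many strata are degenerate
  and are dropped (with the 0.5 correction applied where a margin is
  zero), so its p-value should be read qualitatively at small sizes.
* The cluster-robust variance assumes many PSUs per country; countries
  with few clusters get unstable interval estimates, and such
  countries are skipped (with a logged reason) rather than crashing a
  pipeline run.
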