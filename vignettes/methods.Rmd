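---
title: "Estimating heterogeneous insurance effects with matching and honest causal forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heterogeneous insurance effects with matching and honest causal forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

`hetfx` implements a complete observational-study workflow for estimating
the effect of voluntary health-insurance enrollment on child anthropometric
outcomes, of the kind studied with the CFPS 2018 rural-child sample:
weight-for-height (WHZ), weight-for-age (WAZ) and height-for-age (HAZ)
z-scores for preschool children (ages 0–5), and BMI for school-age children
(6–16). Enrollment is voluntary, so enrolled and uninsured children differ
systematically (enrolled children in such samples are older, poorer, more
rural, with older and less-educated mothers), and a naive group contrast
confounds the insurance effect with those differences.

In the potential-outcomes notation, each child has outcomes $y_{1i}$ (if
enrolled) and $y_{0i}$ (if not), an individual effect
$\alpha_i = y_{1i} - y_{0i}$, and the estimands are the ATE
$E[\alpha_i]$, the ATT $E[\alpha_i \mid W_i = 1]$, the ATC
$E[\alpha_i \mid W_i = 0]$, and the conditional effect
$\tau(x) = E[y_{1i} - y_{0i} \mid X_i = x]$. Identification rests on the
conditional-independence assumption (selection on the observed covariates)
and overlap ($0 < P(W{=}1 \mid x) < 1$).

The package provides two estimation routes plus the infrastructure to test
both against known ground truth:

1. **Propensity-score matching** for the ATT: a logit propensity model,
   common-support trimming, 1:1 and 1:k nearest-neighbor and Epanechnikov
   kernel matching, bootstrap standard errors, and balance diagnostics.
2. **An honest causal forest** for $\tau(x)$: R-learner orthogonalization,
   heterogeneity-maximizing honest trees, adaptive neighborhood weights,
   importance screening with a second-stage refit, subgroup effects, and a
   heterogeneity verdict from the distribution of per-record effects.
3. **A synthetic cohort generator** with confounded enrollment and known
   potential outcomes, so every estimator is exercised end-to-end against
   the truth without any external data.

## The synthetic cohort generator

The generator (`sim_config()`, `simulate_sample()`, `simulate_study()`)
emulates the structure of the emulated sample: 5552 records by default,
roughly 36% preschool, and ~85.7% enrollment. Covariates are drawn from
documented marginals — integer child age uniform on the cohort range;
mother's age as child's age plus a Normal(27, 5) generation gap truncated
to [16, 55]; a 7-level education code weighted toward primary/junior-high
(mean ≈ 2.9); log household income per capita Normal(9.0, 0.95); urban
residence Bernoulli(0.35); a 3-level region code; and a wealth quintile
formed by quintile-ranking log income plus independent Normal(0, 0.3)
jitter. The published tables never state how wealth quintiles were built,
so the jittered-income rank is a documented stand-in: it makes wealth a
noisy relative of income rather than a deterministic recode.

Enrollment is Bernoulli with inverse-logit probability in the covariates.
The default coefficients load negatively on income (−0.55), urban residence
(−0.60) and mother's education (−0.30), positively on child age (0.10),
mother's age (0.04) and region (0.35), with the intercept (5.24) solved
numerically so the marginal enrollment share is 0.857 — the 4760/5552 share
of the emulated cohort. The loadings make enrolled children clearly poorer,
so the naive group contrast understates a positive health effect by about
0.1 outcome-sd at the default settings, which is what gives the matching
and orthogonalization machinery something real to correct.

Outcomes follow the partially linear model
$Y_i = f(X_i) + W_i\,\tau(X_i) + \varepsilon_i$ with a linear baseline
$f$ (per-outcome intercepts plus small loadings on mother's education,
log income, and child age, chosen so each outcome matches its published
scale: z-scores centered near −0.2 to 0.0 with sd ≈ 0.8–1.0, BMI near 18.3
with sd ≈ 5) and Normal noise. The effect function `effect_spec()` is a
baseline $\tau_0$ plus named subgroup increments (e.g. `rural`,
`low_mother_education`) and centered slopes (e.g. `mother_age_slope` per
year of mother's age); the generator returns $y_0$, $y_1$, the realized
$\tau_i = y_1 - y_0$, and the true selection probability for every record.
Every stage draws from its own RNG stream derived from the master seed, so
covariates, enrollment and outcomes are independently reproducible.

What the generator does **not** emulate: survey weights, attrition,
household clustering, panel structure, non-Normal outcome noise, or the
measurement process behind growth-standard z-scores (outcomes are taken as
given numbers). Passing tests therefore demonstrate estimator correctness
under a clean selection-on-observables design, not robustness to those
real-data complications.

## Descriptive comparisons

`summarize_by_group()` reproduces the descriptive-table analysis: per-arm
means and SDs, a difference column, and a two-sample t-test with stars at
the 10/5/1% levels. Two conventions are deliberate and worth flagging:

* **The difference is control − treatment**, matching the published table's
  arithmetic (e.g. a WHZ row of −0.185 treated / −0.376 control prints
  −0.191). This is the reverse of the common treatment−control convention.
* **Welch (unequal-variance) t-test** is the default, since the source
  analysis says only "t-test"; a pooled-variance option exists.

`reference_descriptives()` ships the published group means/SDs. Four of its
printed differences (WAZ, HAZ, gender, region) disagree in the last digit
with arithmetic on the printed rounded means — evidently computed from
unrounded microdata — and are flagged `rounding_consistent = FALSE`; exact
assertions use only the self-consistent rows.

## Propensity-score matching

The propensity model is a logistic regression of enrollment on the child,
mother and household covariates (entered with their integer codes, as in
the descriptive table; one-hot entry is available), fitted by IRLS with
convergence declared when the largest coefficient change drops below 1e-8
(100-iteration cap). Perfect separation and rank-deficient designs raise
explicit errors naming the problem. Common support is the intersection of
the per-arm score ranges; records outside it are excluded from matching.

Matching is with replacement by default — controls are ~14% of the sample,
so without-replacement matching would exhaust the pool — and no caliper is
applied unless requested. Nearest-neighbor matching takes the k closest
in-support controls by |score distance| with weight 1/k each, ties broken
toward the lowest record index (a deterministic, order-independent rule).
Kernel matching weights every in-support control by
$K((p_i - p_j)/h)$, Epanechnikov $K(u) = 0.75(1-u^2)\mathbf{1}\{|u|<1\}$
by default with $h = 0.06$ (the bandwidth used in the emulated analysis;
Gaussian available). A treated unit whose kernel mass is zero is dropped
with a warning and counted. The ATT is the mean over matched treated units
of $Y_i - \sum_j w_{ij} Y_j$.

The published analysis prints standard errors without stating their
method; here they are nonparametric bootstrap SEs (B = 200 by default)
with full re-estimation — propensity refit, support re-trimmed, re-matched —
inside every resample. Balance is diagnosed by standardized mean
differences before and after matching, with the pre-matching arm variances
in the denominator of both so the columns share a scale.

## The honest causal forest

The forest estimates $\tau(x)$ in three steps.

**1. Nuisances.** Conditional-mean and propensity functions
$m(x) = E[Y \mid x]$ (which absorbs $f(x) + p(x)\tau(x)$) and
$p(x) = E[W \mid x]$ are fitted with random regression forests (via
`ranger`), using **out-of-bag predictions** as the cross-fitting device: a
record's nuisance values never depend on its own outcome. Propensity
predictions are clipped to [0.01, 0.99] so treatment residuals are bounded
away from zero.

**2. Orthogonalization.** Residuals $(Y_i - \hat m_i,\; W_i - \hat p_i)$
turn the problem into the residual-on-residual regression whose local
solution over a neighborhood $N$ is
$$\hat\tau_N = \frac{\sum_{i \in N}(W_i - \hat p_i)(Y_i - \hat m_i)}
                    {\sum_{i \in N}(W_i - \hat p_i)^2},$$
first-order insensitive to nuisance estimation error (`local_tau()`).

**3. Honest trees and forest weights.** Each tree takes an independent
half-subsample (without replacement; a with-replacement flag exists for
bootstrap-style fidelity comparisons), splits it 50/50 into a structure
half and an estimation half, and grows greedily on the structure half by
maximizing the heterogeneity criterion
$n_L\hat\tau_L^2 + n_R\hat\tau_R^2$ over candidate thresholds (midpoints of
sorted unique values) of `mtry` randomly drawn covariates. A candidate is
admissible only if both children keep at least `min_leaf` treated and
`min_leaf` control records in **both** halves; splitting stops when no
admissible candidate improves the gain by more than a relative 1e-10, or at
the depth cap. Leaf effects are computed on the estimation half only —
"honesty": the records that shaped the tree never contribute to its
estimates, which the test suite audits directly by perturbing
estimation-half outcomes and asserting the structure is unchanged.

Prediction at $x$ aggregates per-leaf residual sums across trees, which is
algebraically the adaptive-neighborhood weighted estimator
$$\hat\tau(x) = \frac{\sum_i \alpha_i(x)(W_i - \hat p_i)(Y_i - \hat m_i)}
                     {\sum_i \alpha_i(x)(W_i - \hat p_i)^2},\qquad
\alpha_i(x) \propto \tfrac{1}{B}\sum_b \frac{\mathbf{1}\{i \in L_b(x)\}}{|L_b(x)|},$$
with $L_b(x)$ the estimation-half leaf containing $x$ in tree $b$. The
explicit-weight route (`forest_weights()`) and the leaf-sum route
(`predict_cate()`) are verified equal to 1e-12 in the tests, including on
hand-computed small instances.

### Defaults and why

* `min_leaf = 5` per arm per estimation leaf: small enough to resolve
  heterogeneity at n in the low thousands, large enough that every leaf
  ratio is defined. When the goal is a stable constant-effect estimate at
  growing n, leaf size should grow with n (the tests use n/100); with leaf
  size fixed, deeper trees keep per-leaf noise constant and the spread of
  per-record effects does not shrink.
* `mtry = min(⌈√p⌉ + 20, p)`: the reference-software convention rather
  than the classic ⌈√p⌉. With one-hot encoded covariates (p ≈ 20 here),
  √p draws rarely offer the relevant indicator at a node; measured on the
  generator, that starvation attenuated recovered subgroup contrasts by
  roughly a third, which the larger draw removes.
* Covariates are **one-hot encoded** for the forest (so importance can be
  reported per category, e.g. "mother's education: no formal education"),
  unlike the integer coding used in the matching logit.
* Subsampling fraction 0.5 without replacement; honest halves 50/50 (the
  proportions are not dictated by the source description, which says only
  "two sub-samples").
* Tree counts default to 200 (stage 1) and 500 (stage 2) — desk-scale
  settings; the emulated analysis used 1000 and 3000, available via
  configuration. The "500 trees to adjust the parameters" tuning step is
  implemented as a small grid search over `(min_leaf, mtry)` scored by the
  out-of-sample R-learner loss (`tune_causal_forest()`, off by default).

### Screening, subgroups, verdict

`variable_importance()` scores a covariate by its depth-weighted split
frequency: a split at depth d (root = 1) contributes $2^{-d}$, depths
beyond 4 are not counted, scores normalized to sum to one. The source
never defines its importance formula; this decay-by-depth convention is
one of several defensible choices and is documented as such.
`select_covariates()` keeps covariates whose importance strictly exceeds
the mean (1/p); if all are equal, all are kept, so the screen can never
empty the covariate set. `two_stage_fit()` chains screening and the final
refit with shared nuisances.

`cite_distribution_summary()` reports the empirical 2.5–97.5 percentile
interval of the per-record effects and a verdict. The default rule follows
the source's stated reading — an interval straddling 0 is called
"heterogeneous (sign-varying)" — which inverts the conventional reading of
a CI on an average effect; because the intent is ambiguous, the
conventional interpretation is available via `rule = "conventional"`
rather than silently guessed.

`subgroup_effect()` reports CATC (mean per-record effect over a subgroup's
control units) by default, matching the reported estimand, with a CATE
variant. Its SE is the naive sd/√n of the averaged effects — a descriptive
scale, **not** a calibrated forest variance (the published subgroup SEs are
of unstated origin and internally inconsistent with their stars, and are
not emulated). `median_split_profile()` compares covariate means between
records above vs below the median effect (median assigned to the lower
half) with Welch tests.

## Numerical choices and degenerate inputs

* Logit IRLS: tolerance 1e-8 on the max coefficient change; separation
  detected by diverging coefficients (>50) or perfectly separated fitted
  probabilities; rank deficiency reported with the offending columns.
* `local_tau` errors when all treatment residuals are zero; forest
  prediction errors when the weighted residual variance at a query point
  falls below 1e-12; trees whose leaf at a query point has an empty
  estimation set are skipped, and a point skipped by every tree is an
  error.
* Matching tie-breaks are by lowest record index; kernel weights
  renormalize over positive-mass controls only.
* The potential-outcome identity $Y = W y_1 + (1-W) y_0$ holds bit-exactly
  by construction; `tau_true` is stored as the realized $y_1 - y_0$, which
  agrees with the analytic effect function to floating-point rounding
  (asserted at 1e-12).
* A constant nuisance target short-circuits to that constant with a
  warning; records never out-of-bag fall back to the target mean.

## Problem sizes in the test and acceptance runs

The suite exercises oracle identities on ≤10-record hand-built instances;
distributional and recovery checks use n = 1000–4000 with 100–150 trees
(constant-effect recovery, subgroup-contrast recovery, null calibration,
importance screening), n = 20,000–50,000 for cheap marginal checks
(calibration of the enrollment share, no-confounding nulls), and 2000
replicates for the t-test's type-I error. These sizes are the package's
chosen desk scale: large enough that Monte-Carlo noise is well inside the
stated tolerances, small enough to run routinely.

## Known limitations

* Forest confidence intervals (infinitesimal-jackknife variance) are not
  implemented; the CITE interval describes the spread of point estimates,
  not sampling uncertainty, and subgroup SEs are naive.
* The matching estimators target the ATT only; matching-based ATE/ATC are
  out of scope, as are local-linear, spline and Mahalanobis matching.
* Under strongly unbalanced designs (enrollment ~0.86), treatment
  residuals carry little variance, so all residual-ratio estimators are
  noisy at moderate n regardless of implementation; the recovery
  experiments quantify this rather than hide it.
* The generator's conditional-independence design cannot detect bias from
  unobserved confounding; it validates machinery, not identification.
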