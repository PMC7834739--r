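---
title: "Methods: anomalies, latent trends, zonation and survival models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anomalies, latent trends, zonation and survival models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical machinery of `zooptrends`, the
assumptions behind each stage, the tunable parameters with their defaults,
and the design decisions taken where several defensible choices existed. It
states no empirical result beyond what the package's tests and acceptance
script themselves compute.

## 1. Annual biomass anomalies

Net-tow monitoring programs sample unevenly: a handful of tows in some
years, weekly coverage in others, and strong zooplankton seasonality
(multivoltine copepods, ontogenetic vertical migration) superimposed on the
interannual signal of interest. The anomaly engine removes the seasonal
signal and the effort imbalance in three steps:

1. **Seasonal statistic.** Within each season × year cell the *arithmetic*
   mean biomass is taken first and then log10-transformed. Averaging before
   the transform keeps the statistic an unbiased estimate of mean seasonal
   biomass; the log stabilises the variance of strongly right-skewed catch
   data. Seasons are December–February (winter, with December assigned to
   the *following* year's winter), March–May, June–August,
   September–November.
2. **Climatology.** Seasonal means are referenced against the same season's
   mean over a fixed base period (default 1996–2010, a 15-year climatology
   chosen because the consistent record begins in 1996). Seasonal anomalies
   over the base period therefore average to zero by construction — a
   property the tests assert exactly.
3. **Annual anomaly.** The anomaly of a year is the mean of its seasonal
   anomalies over the seasons actually observed. A year qualifies only if
   it has at least one spring or summer observation, the seasons that carry
   most of the biomass signal; winter/fall-only years are dropped rather
   than imputed.

Because the data contain *true* zeros (a taxon absent from a tow) the log
requires the zero-replacement rule: each zero becomes an independent uniform
draw strictly between 0 and half the smallest non-zero value *of that
variable*, scoped across all samples and years. Replacement happens at the
per-sample level, before seasonal averaging, with one RNG substream per
variable derived from a master seed; whether the original analyses replaced
zeros per sample or per seasonal mean is not documented, and per-sample is
the reading most consistent with a per-observation rule. The perturbation is
bounded — a replaced sample moves a seasonal mean by at most half the
minimum non-zero value divided by the sample count — and the bound shrinks
with effort.

Tow selection keeps records from the two deep study regions with bottom
depth > 50 m and tows covering most of the water column (start depth
> 150 m, or ≥ 70% of the column where the bottom is shallower). Daytime
adult euphausiid biomass and abundance are multiplied by 3 before averaging,
offsetting visual net avoidance by large, mobile euphausiids; night tows and
all other groups are untouched.

**Collinearity screen.** Before trend extraction, annual anomaly series with
|Pearson r| > 0.60 (pairwise-complete years) against *two or more* other
series are removed greedily: the most connected variable drops first, ties
break alphabetically, and degrees are recomputed after each removal. "Two or
more" operationalises the qualitative notion of being correlated with
"several" other variables, and the recompute-after-removal rule makes the
procedure deterministic and minimal — it stops as soon as no remaining
variable has two high-correlation partners. A consequence worth knowing: a
perfectly correlated *pair* is retained (each member has only one partner);
the screen targets hubs of redundancy, not all redundancy.

## 2. Physical drivers

Each physical series is reduced to seasonal means at its native cadence and
normalized against the base-period seasonal mean and standard deviation
(sample SD, n−1 — the paper-scale convention is not documented, and the
sample SD is the conventional choice). Annual anomalies average the
normalized seasonal values over available seasons, mirroring the
zooplankton rule. Two derived variables need care:

- **Wind stress** τ = ρ_air·C_D·U², with ρ_air = 1.22 kg m⁻³ and
  C_D = 0.0013. The quadratic is applied *per observation* and then
  averaged: squaring does not commute with averaging, and
  stress-then-average preserves the contribution of wind events. Whether the
  original analysis averaged speed first is unknown; this is the
  package's choice.
- **Annual-event variables** (day of peak river flow, spring-bloom day)
  have one value per year and are normalized at annual cadence directly.
  The peak-flow day requires ≥ 300 daily observations in a year and resolves
  ties to the earliest day.

## 3. Dynamic factor analysis

The DFA expresses m standardized anomaly series as linear combinations of
k < m shared latent trends:

$$x_t = x_{t-1} + w_t, \quad w_t \sim N(0, I_k)$$
$$y_t = Z x_t + v_t, \quad v_t \sim N(0, R)$$

The trends are random walks with unit innovation variance — all scale lives
in the loadings — and the observation error matrix R takes one of four
structures: one shared variance (`diagonal_equal`), per-series variances
(`diagonal_unequal`), compound symmetry with a common variance and common
covariance (`equalvarcov`), or a free symmetric PSD matrix
(`unconstrained`). Identifiability follows the standard DFA convention:
zeros above the diagonal in the first k rows of Z, and a post-fit sign
convention making the largest-magnitude loading on each trend positive.

**Estimation.** EM with an exact Kalman filter/smoother E-step. The initial
state is fixed at zero with a diffuse prior variance of 5 on each trend (the
convention of the widely used state-space DFA implementation this design
follows). Missing observations are handled exactly both in the likelihood
(the filter updates on the observed subvector) and in the M-step sufficient
statistics, where the conditional moments of missing entries given the
observed entries and the smoothed state use the full partitioned-R formulas
— necessary for the two non-diagonal structures. The M-step is conditional
(ECM): the free elements of Z solve a GLS system weighted by R⁻¹ (the zero
constraints couple rows when R has off-diagonal mass), then R is the
structure-constrained MLE of the expected residual covariance; for compound
symmetry that MLE comes from the two-eigenvalue decomposition in the fixed
eigenbasis of the equicorrelation matrix. Both conditional steps increase
the expected complete-data log-likelihood, so the observed log-likelihood is
non-decreasing — asserted on every EM trace in the tests, and validated
against an independent joint-Gaussian likelihood oracle that integrates the
states out analytically.

Numerical defaults: convergence at a relative log-likelihood change below
1e−6, at most 5000 iterations (fits that hit the cap are flagged, retained
and reported), deterministic SVD-based initialization with optional seeded
random restarts. Series are z-scored before fitting by default: anomalies of
different variables sit on different scales and the loadings are only
comparable after standardization. Whether the original analysis z-scored is
undocumented; `fit_dfa(..., zscore = FALSE)` exposes the alternative, and
the acceptance block for the published likelihoods reports the sensitivity
of the result to this choice when the deposited anomaly table is available.

**Model choice.** Candidates over k (default 1..m−1) and the four structures
are ranked by AICc with n equal to the number of non-missing observations
(the convention of the reference state-space implementation; the parameter
count is the free loadings, m·k − k(k−1)/2, plus 1, m, 2 or m(m+1)/2
variance parameters). Akaike weights and cumulative weights accompany the
table. The winning solution is varimax-rotated — an orthogonal rotation of
the loadings with the inverse rotation applied to the trends, so fitted
values are unchanged to machine precision (asserted at 1e−8).

## 4. Chronological zonation

To ask *when* the system shifted, years are clustered under a contiguity
constraint: only temporally adjacent blocks may merge, each merge being the
one that least increases the within-group sum of squares (incremental
sum-of-squares agglomeration on the latent-trend matrix, used as-is since
DFA trends are already on a common scale). The number of significant zones
comes from a broken-stick comparison: the proportion of total dispersion
removed by the k-th split is compared with the Monte-Carlo expectation of
the (k−1)-th largest segment of a stick broken at random into T−1 pieces
(1000 random sticks by default, seeded); the significant zone count is the
largest k whose every split beats its random expectation. This
randomization form follows the cited zonation literature; the test suite
verifies it reports one zone on exchangeable noise and recovers constructed
block structures.

A known property of greedy agglomeration: the 2-cluster level of the tree
is not guaranteed to be the globally optimal single cut on arbitrary data
(the greedy dispersion is only an upper bound, which the tests check
against exhaustive enumeration for short sequences). When genuine zone
structure exists the two coincide, and the tests assert exact agreement in
that regime.

## 5. Survival models: the regression ladder

Marine survival proportions p (hatchery release to age 2 for Chinook, total
marine survival for Coho) are transformed to α = logit(p) and standardized;
the stored centre and scale allow exact back-transformation,
S = inv_logit(α·scale + centre). Years flagged preliminary (incomplete
returns) are excluded from both the centring statistics and the fit, and
handled as prediction-only years. The modelling protocol is staged:

1. **Stationarity.** KPSS tests for level and trend stationarity of the
   response (Bartlett long-run variance, short truncation lag, p-values
   interpolated from the standard table and clamped to [0.01, 0.1]). If
   either p < 0.05 the response and all covariates are first-differenced
   and retested; p-values within 0.005 of the threshold are accepted with a
   warning, since the later residual diagnostics re-check autocorrelation.
2. **Best subsets.** Exhaustive enumeration of all covariate subsets of
   sizes 1–5 (no interactions), minimum RSS per size, complete cases only,
   rank-deficient subsets skipped with a warning.
3. **Error structure.** Each size-winner is refit as a regression with ARMA
   errors over a grid p, q ∈ 0..3, d ∈ 0..1 (no seasonal terms — annual
   series of ~20 points support nothing richer), by maximum likelihood;
   the order minimizing AICc wins. (0,0,0) means plain uncorrelated
   errors. A caveat by construction: AICc values for d = 0 and d = 1 are
   computed on different effective series, so cross-d comparisons are
   heuristic; the KPSS stage is the principal guard against unit roots.
4. **Top model.** Valid candidates need every covariate's 95% CI to exclude
   zero and a Ljung-Box residual p > 0.05; among valid candidates the
   lowest AICc wins, with a nested-model F-test deciding ties within 2 AICc
   units (significant → larger model). If nothing passes, the caller
   receives an explicit "no valid model" — with many candidate covariates
   and ~20 years this filter is deliberately conservative, and a test
   quantifies the implied type-I behaviour on pure-noise covariates.
5. **OLS finalization.** When the selected order is (0,0,0) an OLS refit
   supplies the adjusted R², the overall F-test p-value and diagnostic
   tables (residuals vs fitted, QQ, leverage).

Predictive skill uses 5-repeat 5-fold cross-validation with the CV R²
defined as the squared Pearson correlation between pooled out-of-fold
predictions and observations, averaged over repeats — the convention of the
common CV tooling, pinned here for reproducibility. Prediction intervals
for unfitted years come from the OLS prediction-variance formula (parameter
plus residual variance) and are back-transformed through the monotone
inverse-logit chain, preserving interval ordering; models selected with a
non-(0,0,0) order fall back to their regression component for prediction,
with a warning.

## 6. Sampling-effort simulation

Could uneven effort alone produce an apparent run of low-biomass years? The
resampling module re-answers that question on any record pool: each
repetition subsamples the target years down to a fixed number of tows
(default 12, the historical sparse-era average), recomputes the *entire*
anomaly pipeline, and records the annual anomalies; the run probability is
the fraction of repetitions containing ≥ 5 consecutive years below −0.10.
Draws are without replacement and stratified by season in proportion to a
sparse-era seasonal profile — an unstratified draw from a dense, seasonally
balanced pool would conflate effort *level* with seasonal *coverage*, and
the historical low-effort years were strongly seasonally skewed. The exact
stratification of the original simulation is not documented; this
reconstruction is the package's choice. Two identities anchor correctness:
subsampling at census size reproduces the full-data anomalies exactly, and
the run probability matches closed-form Bernoulli oracles.

The published run probability (P = 0.00032) and the percent-composition
figures depend on the full monitoring database and cannot be recomputed
from shipped material; the module reproduces the procedure, validated by
the oracles above.

## 7. The synthetic-data generator

The generator is first-class, tested code that defines the study conditions
under which the pipeline is exercised:

- **Zooplankton records.** k = 2 latent random-walk trends (innovation SD
  0.25 in log10 units) drive 12 taxonomic groups through fixed loading
  vectors; per-tow biomass is lognormal around the seasonal mean (per-sample
  SD 0.35 log10 units, with the meanlog offset so the *arithmetic* mean
  matches the target — the quantity the anomaly statistic estimates); true
  zeros are injected per group at rates from 1% (abundant copepods) to 15%
  (rare gelatinous groups and fish larvae); sampling effort follows the
  printed seasonal effort table of the monitoring program (4–27 tows/year
  in the sparse era, 61–156 after 2014), and records carry depths, regions
  and day/night flags satisfying the selection rules.
- **Physical drivers.** AR(1)+trend series at native cadence (daily SST/SSS
  and flow, monthly climate index, annual bloom day), with wind stress and
  peak-flow day computed from the simulated primitives, not drawn directly.
  Parameters (means, SDs, AR coefficients, trends) are set to oceanographically
  plausible magnitudes for a temperate estuarine system.
- **Survival.** Standardized logit survival is linear in named covariates
  plus Gaussian noise, inverted to proportions through the centre/scale
  constants; generating coefficients are stored for recovery tests.

What the generator deliberately does **not** emulate: species-level
composition within groups, spatial station structure, day/night behavioural
differences beyond the euphausiid flag, covariance between physical drivers
and zooplankton trends (drivers are independent of the biology unless the
survival model links them), and observation error in the physical series.
Passing tests therefore demonstrate the *pipeline's* correctness and
recoverability under realistic sampling noise — not that the real ecosystem
satisfies the generative assumptions.

## 8. Problem sizes used by the test suite

The property and recovery studies run at sizes chosen to make the suite a
routine desk check: EM monotonicity on 100 random 4-series × 12-year
instances; varimax invariance on 25 fits; CONISS-vs-enumeration on
sequences of 5–8 years; best-subsets equivalence at 12 candidate
covariates; prediction-interval coverage over 400 simulated refits;
trend-count recovery on 100 generator replicates at the full 23-year uneven
effort design, searched over k ∈ {1,2,3} × the two diagonal structures; and
survival-covariate recovery on 100 replicates with a strong
single-covariate signal. Recovery rates are reported as test messages.
The acceptance script regenerates everything from a single seed and reports
only quantities computed in that run.

## 9. Known limitations

- AICc comparisons across differencing orders (step 3 above) are heuristic.
- The broken-stick zonation test is conservative for weakly separated
  regimes, and greedy agglomeration need not find the globally optimal
  partition on unstructured data.
- With ~20 candidate covariates and ~20 years, step 4's filter controls
  but does not eliminate selection effects; cross-validated skill is the
  more honest performance measure, and the prediction intervals do not
  account for model-selection uncertainty.
- The KPSS p-values are interpolated within the standard table and clamped
  at its edges (0.01–0.1), as in the common implementations.
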