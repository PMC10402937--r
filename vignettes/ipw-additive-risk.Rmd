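---
title: "Stabilized IPW additive-risk models for long-term exposure cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stabilized IPW additive-risk models for long-term exposure cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ipwadd` estimates *additive* associations — absolute risk differences, not
hazard or odds ratios — between long-term air pollutant exposures and the
incidence of a first cancer diagnosis in large open cohorts of older adults,
in the presence of confounding and a competing risk of death. This vignette
is the package's account of the method: the model, its assumptions, the
tunable parameters, what the synthetic-data generator does and does not
emulate, and the numerical choices that an analyst should know about.

## The design

The analysis unit is the **person-year**: one beneficiary observed for one
calendar year. A beneficiary enters the risk set only after a ten-year
cancer-free run-in following enrollment (this guarantees the first observed
diagnosis is incident, not prevalent) and is censored at the first of
diagnosis, death, or the administrative end of study. Each person-year
carries six exposures: moving averages of PM2.5 (µg/m³) and NO2 (ppb) over
lag 0–2 years (the index year and the two before), lag 3–5 years, and lag
6–10 years, linked through the ZIP code of residence in each lagged year.
The three windows of a pollutant partition the 11-year history, so
`(3·lag02 + 3·lag35 + 5·lag610)/11` is exactly the 11-year mean — a useful
invariant that the tests exploit.

Each of the six windows is analyzed in turn as "the" exposure $x_i$, with
the **other five windows included among the confounders** $c_i$, along with
individual covariates (sex, race, Medicaid enrollment, age group at the
start of follow-up: 75–84 vs ≥85) and ZIP-year community covariates. The
estimand is the coefficient $\beta_1$ in the linear probability model

$$E(Y_i = 1 \mid x_i) = \beta_0 + \beta_1 x_i,$$

the additive increase in annual diagnosis probability per unit exposure.

### Stage 1: stabilized weights

Confounding and informative mortality are handled by a stabilized
inverse-probability weight per person-year:

$$sw_i \;=\; \frac{K_{num}(x_i - \bar x)}{K_{den}\!\big(x_i - \hat g(x_i \mid c_i)\big)}
\times \frac{\hat g(D_i = 0 \mid x_i)}{\hat g(D_i = 0 \mid x_i, c_i)}.$$

* $\hat g(x\mid c)$ is a gradient-boosted regression (squared-error loss) of
  the exposure on the confounders — a flexible stand-in for the generalized
  propensity score's conditional mean. Its residuals are the evidence about
  the conditional exposure density.
* $K_{num}$ and $K_{den}$ are **separate** Gaussian kernel densities, fit on
  the centered exposures $\{x_j - \bar x\}$ and on the residuals
  $\{x_j - \hat g\}$ respectively. A single density cannot serve both roles:
  each factor must be a proper density of its own argument's distribution
  for the ratio to be a valid stabilized weight.
* The final factor is a ratio of boosted survival probabilities, the
  competing-risk correction: person-years whose covariates make death likely
  are under-represented among observed survivors and are weighted back up.

### Stage 2: weighted linear probability model and case counts

Weighted least squares of $Y$ on the single target exposure with weights
$sw_i$ gives $\hat\beta_1$; the default standard error is the
heteroskedasticity-robust sandwich clustered on beneficiary (person-years of
one person are correlated), with a person-level nonparametric bootstrap as
an alternative. Stage-1 estimation uncertainty is *not* propagated into
stage-2 standard errors — the usual IPW practice, and a documented
limitation.

The coefficient converts to an annual attributable case count via

$$\text{annual cases} = \hat\beta_1 \times N / \text{duration},$$

with the confidence bounds transformed identically. For the denominator
$N$, `run_pipeline()` reports both conventions — all observation years
including the run-in and the excluded beneficiaries' years (the default),
or analysis person-years only — because printed cohort tables are
ambiguous between the two. Case counts are held at full precision and
rounded half-away-from-zero only at report time. Because the six analyses
are mutually adjusted and additive, the three window estimates of one
pollutant can be *summed* (`combine_windows()`) into a 10-year total; no
interval is attached to the sum.

### Secondary analyses

`run_restricted()` re-runs the entire two-stage pipeline on person-years
whose three windows of the analyzed pollutant all lie **strictly below** a
threshold (defaults: 10 µg/m³ / 20 ppb for the low-level analysis, 5 µg/m³
/ 10 ppb for the WHO-guideline analysis). "Below" is read as strict;
boundary person-years are rare and the choice is recorded in the row
provenance. The restriction applies to the analyzed pollutant only, with a
`both_pollutants` switch. `run_subgroups()` stratifies on a categorical
axis, or on the lower vs upper **person-year quartile** of a continuous
community covariate (boundaries inclusive); weights are always re-estimated
within the stratum. Strata below a configurable guard (default 5,000
person-years and 20 events) yield an `NA` row with a reason code.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| GBM trees / learning rate / depth / subsample | 500 / 0.05 / 3 / 0.8 | conventional boosting regime; no hyperparameters are prescribed by the design, so all are exposed in `design_spec()` |
| Death-model loss | `bernoulli` | logistic loss is the statistically sound choice for a binary indicator; `gaussian_literal` (squared error on 0/1, clipped predictions) is offered for strict comparability with formulations that state a gaussian loss throughout |
| KDE bandwidth | Silverman's rule × `adjust` | standard default; logged in the weight report |
| Weight truncation | cap at (1st, 99th) percentiles | density-ratio weights are heavy-tailed; capping trades a small downward mean shift for bounded variance. `truncation = NULL` disables it |
| Survival-probability clipping | [10⁻³, 1−10⁻³] | keeps the death factor finite |
| Stratum guards | 5,000 person-years, 20 events | below this a linear probability fit on a rare outcome is noise |

The weight diagnostics report the mean weight both **before and after**
truncation, plus the effective sample size $ESS = (\sum w)^2 / \sum w^2$.
The stabilization property — mean weight near 1 — is a property of the
weight *as constructed* and is checked pre-truncation; ESS is reported for
the capped weights actually used in stage 2, since that is the information
the fit retains. On well-specified synthetic cohorts of ~200,000
person-years the pre-truncation mean sits within a few percent of 1 and the
capped ESS fraction around 0.6.

## The synthetic cohort generator

Restricted administrative data cannot ship with a package, so every stage
is exercised against `simulate_cohort()`, a generator that reproduces the
*statistical structure* the estimator assumes, with exported ground truth:

* an open cohort (default 2000–2016) of beneficiaries entering at age 65+,
  each with sex, race, Medicaid status, an enrollment age (so the age-group
  covariate at the start of follow-up is derivable), and a residence ZIP;
* annual ZIP-level exposure surfaces: ZIP mean + linear secular trend +
  AR(1) anomaly, with exposure history extending ten years before cohort
  start so all lag windows are complete; negative concentrations truncate
  at zero (an error if more than 10% truncate);
* three standardized community covariates per ZIP; the deprivation
  covariate `adi` optionally shifts the exposure mean
  (`confounding_strength`, in pollutant units per SD), creating genuine
  confounding when it also carries a risk effect;
* per calendar year, death occurs first (probability additive in current
  PM2.5 and the confounders), then, among survivors, a first diagnosis
  (probability additive in the six lag windows and the confounders). Death
  literally competes with diagnosis, and diagnoses that would have occurred
  in a death year are masked — the mechanism the competing-risk factor
  addresses. Probabilities are clipped to [0,1]; clipping of more than 1%
  of realized person-years aborts the run, because it would silently bend
  the linear truth the recovery tests rely on.

Default values are patterned on published summaries of the US elderly
population and ambient pollution over 2000–2016: PM2.5 mean 9.8 µg/m³
(declining), NO2 mean 17.3 ppb, annual marginal SDs of roughly 2.5 and 8, a
baseline annual diagnosis probability of 7×10⁻⁴ (a colorectal-like rate),
window coefficients of a few 10⁻⁵ per unit, and a baseline annual death
probability of 4.5%.

One generator choice deserves emphasis: the split of exposure variance
between the persistent between-ZIP component (`spatial_sd`) and the
year-to-year AR(1) innovation. Because the three windows of a pollutant
share the ZIP's persistent level, a generator dominated by spatial variance
makes the six windows nearly collinear; the conditional density of the
target window given the other five then has far smaller spread than its
marginal density, and the density-ratio weight has *infinite variance*
(this happens when the conditional SD drops below the marginal SD divided
by √2 in the Gaussian approximation). The defaults keep the windows only
moderately collinear (exposure-model R² ≈ 0.4–0.5), so the weighting
problem the estimator assumes is actually well-posed. Real exposure
surfaces with stronger spatial persistence would make six-window mutual
adjustment ill-conditioned — a genuine limitation of the design worth
checking (via the reported ESS and exposure-model R²) on any real dataset.

What the generator does **not** emulate: daily time series, true geodesic
ZIP polygons, cancer latency and staging, age as a continuous variable, or
measurement error in the exposure surfaces. Passing recovery tests
therefore demonstrate estimator correctness under the assumed structure,
not robustness to violations of it.

## Simulation studies and problem sizes

The test suite verifies the estimator by parameter recovery, at problem
sizes chosen to balance Monte Carlo resolution against a test suite that
runs in minutes:

* **Unconfounded recovery** — 20 replicates of 50,000 beneficiaries
  (~200,000 person-years each; an open 2000–2022 cohort with a 3% baseline
  death rate yields that ratio) with a single true window coefficient
  5×10⁻⁵: the replicate-mean IPW estimate must land within ±30% of truth
  and within 2 Monte Carlo SEs, and weighted and unweighted estimates must
  agree within Monte Carlo error.
* **Confounded recovery** — the same scale, with the deprivation covariate
  shifting exposure by +1 unit and risk by +2×10⁻⁴ per SD. The unweighted
  slope is predictably biased upward; per replicate the bias is detected by
  the *paired* sign of (unweighted − IPW), which cancels the sampling noise
  the two estimators share — a sign test against the truth alone would have
  only ~85% per-replicate power at this scale. The IPW estimate must sit
  within 2 Monte Carlo SEs of truth.
* **Competing-risk correction** — 20 replicates of 30,000 beneficiaries
  with a high (8%) death rate strongly driven by the same covariate that
  drives exposure. The estimate using the full weight must be closer to
  truth (in replicate-mean bias) than the kernel-ratio-only weight. Under
  the per-person-year death-model formulation this correction is
  second-order — it repairs the covariate-dependent masking of diagnoses by
  same-year deaths — so the margin is real but small.
* **Oracle equivalences** — weighted least squares against the closed-form
  weighted normal equations (relative error < 10⁻¹⁰); grid-to-ZIP
  aggregation against a brute-force ray-casting containment oracle on 100
  random instances; estimated weights against closed-form normal densities
  in a two-strata design whose strata means sit 1 SD apart (wider
  separation makes the true weight surface flat at the stratum proportions
  for most observations, so rank agreement among the resulting near-ties
  measures nothing).

Simulation-study boosting uses 150 trees at learning rate 0.1 — the
confounding signals in the generator are smooth and low-dimensional, and
this captures them at a fraction of the default fitting cost.

## Numerical choices and degenerate inputs

* KDE evaluation is exact (mean of Gaussian kernels) up to 5,000 sample
  points and grid-interpolated (4,096 points spanning the sample range ±8
  bandwidths) above; the fitted density is verified to integrate to 1
  within 10⁻³. Zero-variance samples are an error.
* Weights must be finite and positive; offending person-years are named in
  the error. A constant target exposure is an error (weights undefined).
* A cohort with no deaths degenerates the competing-risk factor to 1 with
  a warning rather than an error; a cohort that is all deaths is an error.
* All-zero outcomes give $\hat\beta_1 = 0$ with a degenerate-SE warning.
* Missing exposures or covariates abort person-year assembly with the
  offending person/ZIP/year named; lag windows are never silently imputed
  or shortened.
* `n_trees = 0` degenerates the exposure model to the sample mean, which
  is occasionally useful as a null design.
* Reproducibility: a single seed fans out to fixed per-stage streams, and
  boosting runs single-threaded with a seeded subsample, so identical
  configurations give byte-identical outputs; every `fits.csv` row carries
  the seed and sizes needed to re-run it in isolation.
* Ties at restriction thresholds are excluded (strict `<`); ties at
  subgroup quartile boundaries are included on both ends of the same
  stratum (≤ Q1, ≥ Q3), never in both strata.

## Known limitations

* Stage-1 uncertainty is not propagated; intervals are conditional on the
  estimated weights.
* The per-person-year death models follow the formulation's indexing; a
  cumulative (product-over-years) survival weight is the natural extension
  and would strengthen the competing-risk correction, but is out of scope.
* The additive model is strictly linear in the exposure; restriction
  analyses are the only probe of nonlinearity.
* Community covariates confound at ZIP level only; individual-level
  lifestyle confounding has no analogue in the generator.
* With strongly spatially persistent exposure surfaces the six-window
  mutual adjustment approaches ill-posedness (see above); monitor the
  exposure-model R² and ESS.
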