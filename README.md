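# ipwadd

Additive risk of long-term air pollution exposure in open elderly
cohorts, with confounding and a competing risk of death handled by
stabilized inverse-probability weighting.

## What it does

Large administrative cohorts (e.g., Medicare claims) make it possible to
ask how a decade of exposure to PM2.5 and NO2 changes the *absolute*
probability of a first cancer diagnosis — a quantity more directly
interpretable than a hazard ratio, because it converts into attributable
cases. `ipwadd` implements the full two-stage design for that question:

1. **Design stage.** For a target exposure window `x` (one of PM2.5 or NO2
   averaged over lag 0–2, 3–5 or 6–10 years), each person-year receives a
   stabilized inverse-probability weight

   ```
   sw_i = K_num(x_i − x̄) / K_den(x_i − ĝ(x_i | c_i)) × ĝ(D_i=0 | x_i) / ĝ(D_i=0 | x_i, c_i)
   ```

   where `ĝ(x|c)` is a gradient-boosted regression of the exposure on the
   confounders `c` (the other five windows, individual covariates, and
   ZIP-year community covariates), `K_num`/`K_den` are Gaussian kernel
   densities of the centered exposures and of the exposure residuals, and
   the last factor — a ratio of boosted survival probabilities — corrects
   for the competing risk of death.

2. **Analysis stage.** A weighted linear probability model
   `E(Y=1|x) = β0 + β1·x` gives the risk difference `β1` per unit exposure
   (cluster-robust or bootstrap SEs by beneficiary), which converts to
   annual attributable cases via `β1 × N / duration` and sums across the
   three mutually adjusted windows of a pollutant.

Around the estimator the package provides cohort construction (10-year
cancer-free run-in, censoring at diagnosis/death/end of study),
distributed-lag window computation, grid-to-ZIP exposure aggregation,
low-exposure restriction and subgroup analyses, a reproducible pipeline
driver, ggplot2 `autoplot()` views, and a synthetic open-cohort generator
with exported ground truth so every stage is testable without restricted
data.

## Worked example

Simulate a confounded open cohort (community deprivation raises both
exposure and cancer risk), build the person-year table, and run both
stages for PM2.5 at lag 0–2:

```r
library(ipwadd)

cfg <- sim_config(n_individuals = 20000, study_end = 2022,
                  confounding_strength = 1, seed = 42)
sim <- simulate_cohort(cfg)
cohort <- apply_inclusion_and_censor(sim$persons, cfg$study_end)
py <- assemble_person_years(cohort$included, sim$zip_exposures, sim$zip_covariates)

spec <- design_spec("pm25_lag02",
                    gbm_params = list(n_trees = 150, learning_rate = 0.1),
                    seed = 42)
ws <- stabilized_weights(py, spec)
ws
#> Stabilized IPW for pm25_lag02: n = 45264, mean = 0.841, max = 5.705, ESS = 23726 (52.4%)
#> covariates with weighted |association| above threshold: pm25_lag35, pm25_lag610, adi

fit <- weighted_lpm(py, ws)
tidy(fit)
#> # A tibble: 2 × 5
#>   term        estimate std.error   conf.low conf.high
#>   <chr>          <dbl>     <dbl>      <dbl>     <dbl>
#> 1 (Intercept) 0.00130  NA        NA         NA
#> 2 pm25_lag02  0.000111  0.000107 -0.0000993  0.000320
```

The weights center near 1 and retain 52% of the sample as effective
information; the two longer PM2.5 windows stay associated with the target
window (they share the ZIP's persistent level — expected, and why they are
adjusted as confounders). The fitted risk difference 1.1×10⁻⁴ per µg/m³
has a wide interval at this small scale (86 events) but covers the
generator's truth of 4.7×10⁻⁵, while the unweighted slope (1.5×10⁻⁴) is
pulled upward by confounding and by the other windows' effects. Converting
to attributable cases over the whole observed cohort:

```r
N_total <- sum(cohort$included$censor_year - cohort$included$enroll_year + 1) +
  sum(cohort$exclusions$obs_years)
annual_cases(fit, N = N_total, duration = 23)
#> pm25_lag02: 1 annual cases per unit (95% CI -1, 3); N = 189,616 person-years over 23 years
```

`run_pipeline()` drives the same steps (plus restriction and subgroup
plans for all six windows) from a single YAML/list configuration and
writes `fits.csv` with full per-row provenance; `autoplot(ws)`,
`autoplot(ws$diagnostics$balance)` and `plot_fits()` give the standard
diagnostic and forest plots.

At realistic scale the estimator is accurate: the test suite's recovery
studies (20 replicates × ~200,000 person-years) recover a true
coefficient of 5×10⁻⁵ within Monte Carlo error, with and without
confounding.

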