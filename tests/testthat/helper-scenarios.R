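# Shared scenario builders for the simulation studies.

zero_conf <- c(
  sex_male = 0, race_black = 0, race_other = 0, medicaid = 0,
  age_ge85 = 0, adi = 0, mean_bmi = 0, pop_density = 0
)

# Single-window truth used by the recovery studies: beta1 on pm25_lag02
# only, optional confounding through the area-deprivation covariate, and
# a configurable death process.
scenario_truth <- function(beta1 = 5e-5, gamma_adi = 0,
                           death_base = 0.03, death_adi = 0,
                           death_exposure = 0, beta0 = 7e-4) {
  g <- zero_conf
  g["adi"] <- gamma_adi
  d <- zero_conf
  d["adi"] <- death_adi
  sim_truth(
    beta0_cancer = beta0,
    beta_windows = c(
      pm25_lag02 = beta1, pm25_lag35 = 0, pm25_lag610 = 0,
      no2_lag02 = 0, no2_lag35 = 0, no2_lag610 = 0
    ),
    gamma_confounders = g,
    death_base = death_base,
    death_exposure_coeff = death_exposure,
    death_confounder_coeffs = d
  )
}

# simulate + include + assemble in one step
build_person_years <- function(n, seed, confounding = 0, truth = scenario_truth(),
                               study_end = 2022, n_zips = 1000) {
  cfg <- sim_config(
    n_individuals = n, n_zips = n_zips, study_end = study_end,
    confounding_strength = confounding, truth = truth, seed = seed
  )
  sim <- simulate_cohort(cfg)
  cohort <- apply_inclusion_and_censor(sim$persons, cfg$study_end)
  assemble_person_years(cohort$included, sim$zip_exposures, sim$zip_covariates)
}

# boosting configuration used by the simulation studies: enough trees to
# capture the (smooth, low-dimensional) confounding signals at a
# fraction of the default fitting cost
study_gbm <- list(n_trees = 150, learning_rate = 0.1)

# small confounded cohort shared across test files (built lazily once)
.shared <- new.env(parent = emptyenv())
shared_confounded_cohort <- function() {
  if (is.null(.shared$py)) {
    .shared$py <- build_person_years(
      8000, 424242,
      confounding = 1,
      truth = scenario_truth(beta1 = 5e-5, gamma_adi = 2e-4),
      study_end = 2016
    )
  }
  .shared$py
}

# hand-built person-year table (bypasses the cohort generator) for
# estimator-level tests: x is the target window, remaining windows and
# covariates are configurable
synthetic_py <- function(n, x, y = NULL, d = NULL, seed = 1,
                         extra = list()) {
  withr::with_seed(seed, {
    tab <- tibble::tibble(
      person_id = sprintf("s%06d", seq_len(n)),
      year = 2015L,
      zip = "z00001",
      pm25_lag02 = x,
      pm25_lag35 = stats::rnorm(n),
      pm25_lag610 = stats::rnorm(n),
      no2_lag02 = stats::rnorm(n),
      no2_lag35 = stats::rnorm(n),
      no2_lag610 = stats::rnorm(n),
      sex = "female",
      race = "white",
      medicaid = 0L,
      age_group = "75to84",
      adi = stats::rnorm(n),
      mean_bmi = stats::rnorm(n),
      pop_density = stats::rnorm(n),
      Y = y %||% integer(n),
      D = d %||% integer(n)
    )
    for (nm in names(extra)) tab[[nm]] <- extra[[nm]]
    tab
  })
}

# independent point-in-polygon oracle (ray casting), deliberately coded
# apart from the implementation path
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)) {
      inside <- !inside
    }
    j <- i
  }
  inside
}
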