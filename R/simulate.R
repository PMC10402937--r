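# Synthetic open-cohort generator.
#
# Emulates the statistical structure the two-stage IPW additive-risk
# analysis assumes: an open Medicare-like cohort (annual person-years,
# ages 65+ at entry, 10-year cancer-free run-in), ZIP-level annual
# pollutant surfaces with spatial heterogeneity, a secular trend and AR(1)
# temporal autocorrelation, community covariates that can shift the
# exposure mean (confounding), an exposure- and covariate-dependent death
# process (the competing risk), and a cancer-incidence process that is
# additive in the six lag-window exposures with known coefficients. The
# true coefficients are exported so parameter recovery can be tested.

IND_CONFOUNDERS <- c("sex_male", "race_black", "race_other", "medicaid", "age_ge85")
COMM_CONFOUNDERS <- c("adi", "mean_bmi", "pop_density")

#' Ground-truth parameters of the synthetic cohort
#'
#' Defines the data-generating coefficients: the baseline annual diagnosis
#' probability, the additive risk increment per unit of each lag-window
#' exposure (per ug/m3 for PM2.5 windows, per ppb for NO2 windows),
#' additive confounder effects on diagnosis risk, and the annual death
#' process (baseline, per-unit effect of current-year PM2.5, confounder
#' effects). Defaults reflect an elderly US cohort: a baseline annual
#' diagnosis probability of 7e-4, window coefficients of a few times
#' 1e-5, and a baseline annual death probability of 4.5%.
#'
#' @param beta0_cancer Baseline annual diagnosis probability.
#' @param beta_windows Named numeric of length six (names
#'   [window_names()]): additive annual-risk increment per unit of each
#'   window.
#' @param gamma_confounders Named numeric over the confounders
#'   (`sex_male`, `race_black`, `race_other`, `medicaid`, `age_ge85`,
#'   `adi`, `mean_bmi`, `pop_density`): additive effects on diagnosis risk.
#' @param death_base Baseline annual death probability.
#' @param death_exposure_coeff Additive effect of current-year PM2.5 on
#'   the annual death probability (per ug/m3).
#' @param death_confounder_coeffs Named numeric over the same confounder
#'   set: additive effects on the death probability.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(beta0_cancer = 7e-4,
                      beta_windows = c(
                        pm25_lag02 = 4.7e-5, pm25_lag35 = 4.0e-5,
                        pm25_lag610 = 4.1e-5, no2_lag02 = 5e-6,
                        no2_lag35 = 9e-6, no2_lag610 = 3e-6
                      ),
                      gamma_confounders = c(
                        sex_male = 1e-4, race_black = 1e-4, race_other = 0,
                        medicaid = 2e-4, age_ge85 = 2e-4,
                        adi = 2e-4, mean_bmi = 1e-4, pop_density = 0
                      ),
                      death_base = 0.045,
                      death_exposure_coeff = 1e-3,
                      death_confounder_coeffs = c(
                        sex_male = 0.02, race_black = 0.01, race_other = 0,
                        medicaid = 0.02, age_ge85 = 0.08,
                        adi = 0.01, mean_bmi = 0.005, pop_density = 0
                      )) {
  all_conf <- c(IND_CONFOUNDERS, COMM_CONFOUNDERS)
  beta_windows <- beta_windows[window_names()]
  gamma_confounders <- gamma_confounders[all_conf]
  death_confounder_coeffs <- death_confounder_coeffs[all_conf]
  if (anyNA(beta_windows) || anyNA(gamma_confounders) ||
    anyNA(death_confounder_coeffs)) {
    abort("sim_truth coefficient vectors must cover all windows/confounders")
  }
  names(beta_windows) <- window_names()
  names(gamma_confounders) <- all_conf
  names(death_confounder_coeffs) <- all_conf
  structure(
    list(
      beta0_cancer = beta0_cancer,
      beta_windows = beta_windows,
      gamma_confounders = gamma_confounders,
      death_base = death_base,
      death_exposure_coeff = death_exposure_coeff,
      death_confounder_coeffs = death_confounder_coeffs
    ),
    class = "sim_truth"
  )
}

#' Configuration of the synthetic cohort generator
#'
#' @param n_individuals Number of beneficiaries.
#' @param study_start,study_end Calendar years bounding the open cohort
#'   (defaults 2000 and 2016). `study_end` must exceed
#'   `study_start + 11` so at least one post-run-in analysis year exists.
#' @param n_zips Number of ZIP codes.
#' @param exposure_params Per-pollutant list (`pm25`, `no2`), each with
#'   `spatial_mean` (long-run level), `spatial_sd` (between-ZIP SD of the
#'   level), `ar1_coefficient` in `[0, 1)` (year-to-year autocorrelation of
#'   the within-ZIP anomaly), `innovation_sd` (SD of AR(1) innovations) and
#'   `trend_per_year` (secular linear trend). Defaults emulate US ambient
#'   levels over 2000-2016: PM2.5 mean 9.8 ug/m3 and NO2 mean 17.3 ppb,
#'   both declining. The split between persistent between-ZIP variance
#'   and year-to-year innovation keeps the three windows of a pollutant
#'   only moderately collinear, so that mutually adjusted density-ratio
#'   weights have finite variance (an assumption of the weighting
#'   method; see the vignette).
#' @param confounding_strength Shift of each pollutant's ZIP-level mean per
#'   standard deviation of the area-deprivation covariate `adi` (units of
#'   the pollutant per SD). Zero removes exposure-covariate confounding.
#' @param move_prob Annual probability that a person moves to a random
#'   other ZIP (0 disables residential mobility and the residence table).
#' @param truth A [sim_truth()] object.
#' @param seed Integer seed; identical configurations reproduce
#'   byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 10000,
                       study_start = 2000,
                       study_end = 2016,
                       n_zips = 500,
                       exposure_params = list(
                         pm25 = list(
                           spatial_mean = 9.8, spatial_sd = 1.2,
                           ar1_coefficient = 0.4, innovation_sd = 2.2,
                           trend_per_year = -0.25
                         ),
                         no2 = list(
                           spatial_mean = 17.3, spatial_sd = 4.0,
                           ar1_coefficient = 0.5, innovation_sd = 6.0,
                           trend_per_year = -0.5
                         )
                       ),
                       confounding_strength = 1.0,
                       move_prob = 0,
                       truth = sim_truth(),
                       seed = 1L) {
  if (study_end <= study_start + 11) {
    abort("study_end must exceed study_start + 11")
  }
  for (p in c("pm25", "no2")) {
    ep <- exposure_params[[p]]
    if (is.null(ep)) abort(paste0("exposure_params must include '", p, "'"))
    if (ep$ar1_coefficient < 0 || ep$ar1_coefficient >= 1) {
      abort("ar1_coefficient must lie in [0, 1)")
    }
    if (ep$spatial_sd < 0 || ep$innovation_sd < 0) {
      abort("spatial_sd and innovation_sd must be nonnegative")
    }
  }
  if (!inherits(truth, "sim_truth")) abort("truth must be a sim_truth()")
  stopifnot(
    n_individuals >= 1, n_zips >= 1,
    move_prob >= 0, move_prob <= 1
  )
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      study_start = as.integer(study_start),
      study_end = as.integer(study_end),
      n_zips = as.integer(n_zips),
      exposure_params = exposure_params,
      confounding_strength = confounding_strength,
      move_prob = move_prob,
      truth = truth,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate ZIP-level community covariates
#'
#' Three standardized continuous community covariates per ZIP, constant
#' over the study years: `adi` (area deprivation), `mean_bmi` and
#' `pop_density`. `adi` is the covariate that [sim_config()]'s
#' `confounding_strength` couples to the exposure surface.
#'
#' @param config A [sim_config()].
#' @return Tibble with one row per ZIP: `zip`, `adi`, `mean_bmi`,
#'   `pop_density`.
#' @export
simulate_zip_covariates <- function(config) {
  withr::with_seed(derive_seed(config$seed, "covariates"), {
    tibble::tibble(
      zip = sprintf("z%05d", seq_len(config$n_zips)),
      adi = rnorm(config$n_zips),
      mean_bmi = rnorm(config$n_zips),
      pop_density = rnorm(config$n_zips)
    )
  })
}

#' Simulate the annual ZIP-level exposure surface
#'
#' For each pollutant and ZIP the annual series is
#' `spatial_mean + spatial_sd * eta_zip + confounding_strength * adi_zip +
#' trend_per_year * (year - study_start) + AR(1) anomaly`, with the AR(1)
#' anomaly started from its stationary distribution. The surface covers
#' `study_start - 10` through `study_end` so lag 6-10 windows are complete
#' from the first cohort year onward. Negative concentrations are
#' truncated at zero; the truncation count per pollutant is attached as an
#' attribute and truncation of more than 10% of values is an error.
#'
#' @param config A [sim_config()].
#' @param zip_covariates Optional output of [simulate_zip_covariates()];
#'   generated from `config` when omitted.
#' @return Long tibble (`zip`, `year`, `pollutant`, `conc`) with
#'   attributes `truncated` (named count per pollutant) and
#'   `zip_covariates`.
#' @export
simulate_exposure_surface <- function(config, zip_covariates = NULL) {
  if (is.null(zip_covariates)) {
    zip_covariates <- simulate_zip_covariates(config)
  }
  years <- (config$study_start - 10L):config$study_end
  n_years <- length(years)
  n_zips <- config$n_zips
  truncated <- c(pm25 = 0L, no2 = 0L)
  out <- withr::with_seed(derive_seed(config$seed, "exposure"), {
    purrr::map(c(pm25 = "pm25", no2 = "no2"), function(p) {
      ep <- config$exposure_params[[p]]
      mu <- ep$spatial_mean + ep$spatial_sd * rnorm(n_zips) +
        config$confounding_strength * zip_covariates$adi
      rho <- ep$ar1_coefficient
      e <- matrix(0, n_zips, n_years)
      stat_sd <- if (ep$innovation_sd > 0) {
        ep$innovation_sd / sqrt(1 - rho^2)
      } else {
        0
      }
      e[, 1] <- rnorm(n_zips, 0, stat_sd)
      for (t in seq_len(n_years - 1) + 1) {
        e[, t] <- rho * e[, t - 1] + rnorm(n_zips, 0, ep$innovation_sd)
      }
      conc <- outer(mu, rep(1, n_years)) +
        outer(rep(1, n_zips), ep$trend_per_year * (years - config$study_start)) +
        e
      n_trunc <- sum(conc < 0)
      if (n_trunc > 0.10 * length(conc)) {
        abort(paste0(
          "more than 10% of simulated ", p,
          " concentrations were negative and truncated at 0"
        ))
      }
      conc[conc < 0] <- 0
      list(
        tab = tibble::tibble(
          zip = rep(zip_covariates$zip, times = n_years),
          year = rep(years, each = n_zips),
          pollutant = p,
          conc = as.vector(conc)
        ),
        n_trunc = n_trunc
      )
    })
  })
  truncated <- purrr::map_int(out, "n_trunc")
  surface <- dplyr::bind_rows(purrr::map(out, "tab")) %>%
    dplyr::arrange(.data$pollutant, .data$zip, .data$year)
  attr(surface, "truncated") <- truncated
  attr(surface, "zip_covariates") <- zip_covariates
  surface
}

#' Simulate the beneficiary population with competing death
#'
#' Each beneficiary gets an enrollment year, an age at enrollment (65+),
#' demographics and a ZIP; follow-up then proceeds year by year from
#' enrollment. In each year death occurs first with probability
#' `death_base + death_exposure_coeff * pm25(t) + sum(death coeffs * c)`;
#' conditional on survival, a first cancer diagnosis occurs with
#' probability `beta0_cancer + sum(beta_windows * x_window(t)) +
#' sum(gamma * c)`. Follow-up stops at the first event; death therefore
#' literally competes with diagnosis. Probabilities are clipped to
#' `[0, 1]`; clipping of more than 1% of realized person-years is an
#' error, because it would invalidate recovery of the linear truth.
#'
#' @param config A [sim_config()].
#' @param exposures Output of [simulate_exposure_surface()].
#' @param zip_covariates ZIP covariate table; taken from the `exposures`
#'   attribute when omitted.
#' @return List with `persons` (tibble: `person_id`, `sex`, `race`,
#'   `medicaid`, `enroll_age`, `enroll_year`, `zip`, `death_year`,
#'   `cancer_year`), `residences` (long residence history, or `NULL` when
#'   mobility is off) and `truth_report` (the [sim_truth()] plus realized
#'   event counts and the clipping fraction).
#' @export
simulate_population <- function(config, exposures, zip_covariates = NULL) {
  if (is.null(zip_covariates)) {
    zip_covariates <- attr(exposures, "zip_covariates")
  }
  if (is.null(zip_covariates)) {
    abort("zip_covariates must be supplied (or attached to `exposures`)")
  }
  truth <- config$truth
  windows <- zip_lag_windows(exposures)

  withr::local_seed(derive_seed(config$seed, "population"))
  n <- config$n_individuals
  persons <- tibble::tibble(
    person_id = sprintf("p%07d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.4, 0.6)),
    race = sample(c("white", "black", "other"), n,
      replace = TRUE, prob = c(0.91, 0.05, 0.04)
    ),
    medicaid = rbinom(n, 1, 0.11),
    # entry age 65+, ~15% reaching 85+ by the end of the 10-year run-in
    enroll_age = 65L + pmin(floor(stats::rexp(n, rate = 0.19)), 34),
    enroll_year = sample(
      config$study_start:(config$study_end - 8L), n,
      replace = TRUE
    ),
    zip = sample(zip_covariates$zip, n, replace = TRUE)
  )

  # person-year lattice over the whole enrollment span; residence history
  ny <- config$study_end - persons$enroll_year + 1L
  lattice <- persons[rep(seq_len(n), ny), ]
  lattice$year <- sequence(ny, from = persons$enroll_year)
  residences <- NULL
  if (config$move_prob > 0) {
    lattice <- lattice %>%
      dplyr::mutate(
        moved = runif(dplyr::n()) < config$move_prob &
          .data$year > .data$enroll_year,
        new_zip = sample(zip_covariates$zip, dplyr::n(), replace = TRUE)
      ) %>%
      dplyr::mutate(
        zip = {
          z <- .data$zip
          for (i in seq_along(z)) {
            if (i > 1 && !.data$moved[i]) z[i] <- z[i - 1]
            if (.data$moved[i]) z[i] <- .data$new_zip[i]
          }
          z
        },
        .by = "person_id"
      ) %>%
      dplyr::select(-"moved", -"new_zip")
    residences <- lattice %>% dplyr::select("person_id", "year", "zip")
  }

  lattice <- lattice %>%
    dplyr::left_join(windows, by = c("zip", "year")) %>%
    dplyr::left_join(zip_covariates, by = "zip")
  if (anyNA(lattice[window_names()])) {
    abort("exposure table does not cover all person-years (lag windows incomplete)")
  }

  conf_mat <- cbind(
    sex_male = as.numeric(lattice$sex == "male"),
    race_black = as.numeric(lattice$race == "black"),
    race_other = as.numeric(lattice$race == "other"),
    medicaid = lattice$medicaid,
    age_ge85 = as.numeric(lattice$enroll_age + 10 >= 85),
    adi = lattice$adi,
    mean_bmi = lattice$mean_bmi,
    pop_density = lattice$pop_density
  )
  p_death_raw <- truth$death_base +
    truth$death_exposure_coeff * lattice$pm25 +
    as.vector(conf_mat %*% truth$death_confounder_coeffs)
  p_cancer_raw <- truth$beta0_cancer +
    as.vector(
      as.matrix(lattice[window_names()]) %*% truth$beta_windows
    ) +
    as.vector(conf_mat %*% truth$gamma_confounders)

  # truth must imply probabilities in [0, 1] over the bulk of the
  # generated covariate distribution
  qd <- quantile(p_death_raw, c(0.01, 0.99), names = FALSE)
  qc <- quantile(p_cancer_raw, c(0.01, 0.99), names = FALSE)
  if (qd[1] < 0 || qd[2] > 1 || qc[1] < 0 || qc[2] > 1) {
    abort(paste0(
      "sim_truth implies annual probabilities outside [0, 1] within the ",
      "1st-99th percentile of generated covariates"
    ))
  }
  p_death <- pmin(pmax(p_death_raw, 0), 1)
  p_cancer <- pmin(pmax(p_cancer_raw, 0), 1)
  clipped <- p_death != p_death_raw | p_cancer != p_cancer_raw

  lattice <- lattice %>%
    dplyr::mutate(
      p_death = p_death, p_cancer = p_cancer, clipped = clipped
    ) %>%
    dplyr::arrange(.data$person_id, .data$year) %>%
    dplyr::mutate(
      dies = runif(dplyr::n()) < .data$p_death,
      diagnosed = !.data$dies & runif(dplyr::n()) < .data$p_cancer
    )

  events <- lattice %>%
    dplyr::mutate(event = .data$dies | .data$diagnosed) %>%
    dplyr::summarise(
      event_year = if (any(.data$event)) min(.data$year[.data$event]) else NA_integer_,
      event_is_death = if (any(.data$event)) .data$dies[which.max(.data$event)] else FALSE,
      .by = "person_id"
    )
  persons <- persons %>%
    dplyr::left_join(events, by = "person_id") %>%
    dplyr::mutate(
      death_year = dplyr::if_else(.data$event_is_death, .data$event_year, NA_integer_),
      cancer_year = dplyr::if_else(
        !.data$event_is_death & !is.na(.data$event_year),
        .data$event_year, NA_integer_
      )
    ) %>%
    dplyr::select(-"event_year", -"event_is_death")

  # person-years actually lived (up to and including the event year)
  lived <- lattice %>%
    dplyr::left_join(
      persons %>%
        dplyr::mutate(
          stop_year = pmin(.data$death_year, .data$cancer_year,
            config$study_end,
            na.rm = TRUE
          )
        ) %>%
        dplyr::select("person_id", "stop_year"),
      by = "person_id"
    ) %>%
    dplyr::filter(.data$year <= .data$stop_year)
  clip_frac <- mean(lived$clipped)
  if (clip_frac > 0.01) {
    abort(sprintf(
      "probability clipping affected %.2f%% of realized person-years (> 1%%); the linear truth is not recoverable under this configuration",
      100 * clip_frac
    ))
  }

  truth_report <- list(
    truth = truth,
    realized = list(
      n_persons = n,
      n_deaths = sum(!is.na(persons$death_year)),
      n_cancer = sum(!is.na(persons$cancer_year)),
      n_person_years_lived = nrow(lived),
      clip_fraction = clip_frac
    )
  )
  list(persons = persons, residences = residences, truth_report = truth_report)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_zip_covariates()],
#' [simulate_exposure_surface()] and [simulate_population()] with seeds
#' derived from the configuration seed, so the whole cohort is
#' reproducible from the `sim_config` alone.
#'
#' @param config A [sim_config()].
#' @return List with `persons`, `residences`, `zip_exposures` (long),
#'   `zip_covariates` (one row per ZIP-year), `truth_report` and the
#'   echoed `config`.
#' @export
simulate_cohort <- function(config) {
  covars <- simulate_zip_covariates(config)
  exposures <- simulate_exposure_surface(config, covars)
  pop <- simulate_population(config, exposures, covars)
  years <- (config$study_start - 10L):config$study_end
  covars_yearly <- tidyr::crossing(covars, year = years) %>%
    dplyr::select("zip", "year", dplyr::all_of(COMM_CONFOUNDERS))
  list(
    persons = pop$persons,
    residences = pop$residences,
    zip_exposures = exposures,
    zip_covariates = covars_yearly,
    truth_report = pop$truth_report,
    config = config
  )
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `persons.csv`, `zip_exposures.csv` (wide: `zip`, `year`, `pm25`,
#' `no2`), `zip_covariates.csv`, `truth.json` and, when mobility is on,
#' `residences.csv`. Missing death/cancer years are empty fields.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$persons, file.path(dir, "persons.csv"), na = "")
  readr::write_csv(
    normalize_exposures(sim$zip_exposures),
    file.path(dir, "zip_exposures.csv")
  )
  readr::write_csv(sim$zip_covariates, file.path(dir, "zip_covariates.csv"))
  if (!is.null(sim$residences)) {
    readr::write_csv(sim$residences, file.path(dir, "residences.csv"))
  }
  truth <- sim$truth_report
  truth$truth <- lapply(unclass(truth$truth), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the CSV files.
#' @return List with `persons`, `zip_exposures` (wide), `zip_covariates`,
#'   `residences` (or `NULL`) and `truth` (or `NULL` if absent).
#' @export
read_cohort <- function(dir) {
  persons <- readr::read_csv(
    file.path(dir, "persons.csv"),
    col_types = readr::cols(
      person_id = "c", sex = "c", race = "c", medicaid = "i",
      enroll_age = "i", enroll_year = "i", zip = "c",
      death_year = "i", cancer_year = "i"
    )
  )
  exposures <- readr::read_csv(
    file.path(dir, "zip_exposures.csv"),
    col_types = readr::cols(zip = "c", year = "i", pm25 = "d", no2 = "d")
  )
  covars <- readr::read_csv(
    file.path(dir, "zip_covariates.csv"),
    col_types = readr::cols(zip = "c", year = "i", .default = "d")
  )
  res_path <- file.path(dir, "residences.csv")
  residences <- if (file.exists(res_path)) {
    readr::read_csv(res_path,
      col_types = readr::cols(person_id = "c", year = "i", zip = "c")
    )
  } else {
    NULL
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path) else NULL
  list(
    persons = persons, zip_exposures = exposures,
    zip_covariates = covars, residences = residences, truth = truth
  )
}
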