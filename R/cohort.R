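# Cohort construction: inclusion with a 10-year cancer-free run-in,
# censoring at the first of diagnosis / death / administrative end of
# study, and assembly of the person-year analysis table.

#' Apply the run-in inclusion rule and censoring
#'
#' A beneficiary enters the risk set only after a 10-year cancer-free
#' run-in: inclusion requires (a) `enroll_year + 10 <= study_end`, (b) no
#' cancer diagnosis and (c) no death strictly before `enroll_year + 10`.
#' Included beneficiaries contribute person-years from
#' `enroll_year + 10` through the first of diagnosis year, death year or
#' `study_end`. Excluded beneficiaries are logged with a reason
#' (`early_cancer`, `early_death`, `insufficient_followup`, or
#' `not_continuously_enrolled` when an `eligible` column is present and
#' 0) together with the calendar years they spent under observation
#' before their own censoring event, so that the attributable-case
#' denominator can optionally include them.
#'
#' @param persons Person table with `person_id`, `enroll_year`,
#'   `death_year`, `cancer_year` (NA = never) and optionally `eligible`
#'   (0/1 continuous-enrollment flag, filtered first).
#' @param study_end Administrative end-of-study year.
#' @return List with `included` (persons plus `followup_start`,
#'   `censor_year`, `event` in `cancer`/`death`/`admin`) and `exclusions`
#'   (tibble `person_id`, `reason`, `obs_years`).
#' @export
apply_inclusion_and_censor <- function(persons, study_end) {
  persons <- tibble::as_tibble(persons)
  obs_end <- pmin(persons$cancer_year, persons$death_year, study_end,
    na.rm = TRUE
  )
  obs_years <- pmax(obs_end - persons$enroll_year + 1L, 0L)
  followup_start <- persons$enroll_year + 10L

  reason <- rep(NA_character_, nrow(persons))
  if ("eligible" %in% names(persons)) {
    reason[persons$eligible == 0] <- "not_continuously_enrolled"
  }
  early_cancer <- is.na(reason) & !is.na(persons$cancer_year) &
    persons$cancer_year < followup_start
  reason[early_cancer] <- "early_cancer"
  early_death <- is.na(reason) & !is.na(persons$death_year) &
    persons$death_year < followup_start
  reason[early_death] <- "early_death"
  reason[is.na(reason) & followup_start > study_end] <- "insufficient_followup"

  keep <- is.na(reason)
  included <- persons[keep, , drop = FALSE] %>%
    dplyr::mutate(
      followup_start = .data$enroll_year + 10L,
      censor_year = pmin(.data$cancer_year, .data$death_year, study_end,
        na.rm = TRUE
      ),
      event = dplyr::case_when(
        !is.na(.data$cancer_year) & .data$censor_year == .data$cancer_year ~ "cancer",
        !is.na(.data$death_year) & .data$censor_year == .data$death_year ~ "death",
        TRUE ~ "admin"
      )
    )
  exclusions <- tibble::tibble(
    person_id = persons$person_id[!keep],
    reason = reason[!keep],
    obs_years = obs_years[!keep]
  )
  list(included = included, exclusions = exclusions)
}

#' Assemble the person-year analysis table
#'
#' One row per included beneficiary per follow-up year, carrying the six
#' lag-window exposures (from the ZIP of residence in each lagged year),
#' the individual confounders, that ZIP-year's community covariates, and
#' the event indicators: `Y = 1` only in the final person-year of a
#' diagnosed beneficiary, `D = 1` only in the final person-year of a
#' beneficiary who died undiagnosed. The age-group confounder is fixed at
#' the start of follow-up (75-84 vs >= 85, i.e. `enroll_age + 10`).
#' Missing exposures or covariates are an error (no silent imputation).
#'
#' @param included `included` element of [apply_inclusion_and_censor()].
#' @param zip_exposures Exposure table (long or wide).
#' @param zip_covariates ZIP-year community covariates (`zip`, `year`,
#'   covariate columns).
#' @param residences Optional residence history (`person_id`, `year`,
#'   `zip`); when supplied, lagged exposures use the ZIP of residence in
#'   each lagged year.
#' @return Tibble of person-years.
#' @export
assemble_person_years <- function(included, zip_exposures, zip_covariates,
                                  residences = NULL) {
  if (nrow(included) == 0) {
    abort("no included persons to assemble")
  }
  ny <- included$censor_year - included$followup_start + 1L
  if (any(ny < 1)) abort("censor_year precedes followup_start")
  py <- included[rep(seq_len(nrow(included)), ny), ] %>%
    dplyr::select(dplyr::any_of(c(
      "person_id", "sex", "race", "medicaid", "enroll_age", "enroll_year",
      "zip", "death_year", "cancer_year", "followup_start", "censor_year",
      "event"
    )))
  py$year <- sequence(ny, from = included$followup_start)

  wide <- normalize_exposures(zip_exposures)
  if (is.null(residences)) {
    windows <- zip_lag_windows(wide)
    py <- dplyr::left_join(py, windows, by = c("zip", "year"))
  } else {
    py <- py %>%
      dplyr::select(-"zip") %>%
      dplyr::left_join(residences, by = c("person_id", "year"))
    # expand each person-year into its 11 lagged (zip, year) lookups
    lagged <- tidyr::crossing(
      py %>% dplyr::select("person_id", "year"),
      lag = 0:10
    ) %>%
      dplyr::mutate(lag_year = .data$year - .data$lag) %>%
      dplyr::left_join(
        residences %>% dplyr::rename(lag_year = "year", lag_zip = "zip"),
        by = c("person_id", "lag_year")
      ) %>%
      # residence history starts at enrollment; before that, use the
      # earliest known residence
      dplyr::left_join(
        residences %>%
          dplyr::slice_min(.data$year, n = 1, by = "person_id", with_ties = FALSE) %>%
          dplyr::select("person_id", first_zip = "zip"),
        by = "person_id"
      ) %>%
      dplyr::mutate(lag_zip = dplyr::coalesce(.data$lag_zip, .data$first_zip)) %>%
      dplyr::left_join(
        wide %>% dplyr::rename(lag_zip = "zip", lag_year = "year"),
        by = c("lag_zip", "lag_year")
      )
    if (anyNA(lagged$pm25)) {
      bad <- lagged[is.na(lagged$pm25), c("person_id", "lag_zip", "lag_year")]
      abort(paste0(
        "missing exposure for e.g. person ", bad$person_id[1], ", zip ",
        bad$lag_zip[1], ", year ", bad$lag_year[1]
      ))
    }
    win_tab <- lagged %>%
      dplyr::summarise(
        pm25_lag02 = mean(.data$pm25[.data$lag <= 2]),
        pm25_lag35 = mean(.data$pm25[.data$lag >= 3 & .data$lag <= 5]),
        pm25_lag610 = mean(.data$pm25[.data$lag >= 6]),
        no2_lag02 = mean(.data$no2[.data$lag <= 2]),
        no2_lag35 = mean(.data$no2[.data$lag >= 3 & .data$lag <= 5]),
        no2_lag610 = mean(.data$no2[.data$lag >= 6]),
        .by = c("person_id", "year")
      )
    py <- dplyr::left_join(py, win_tab, by = c("person_id", "year"))
  }
  if (anyNA(py[window_names()])) {
    bad <- py[!complete.cases(py[window_names()]), c("person_id", "year")]
    abort(paste0(
      "lag exposures unavailable for ", nrow(bad), " person-year(s), e.g. ",
      bad$person_id[1], " in ", bad$year[1]
    ))
  }

  py <- dplyr::left_join(py, zip_covariates, by = c("zip", "year"))
  cov_cols <- setdiff(names(zip_covariates), c("zip", "year"))
  if (anyNA(py[cov_cols])) {
    bad <- py[!complete.cases(py[cov_cols]), c("zip", "year")]
    abort(paste0(
      "community covariates unavailable for zip ", bad$zip[1],
      ", year ", bad$year[1]
    ))
  }

  py %>%
    dplyr::mutate(
      age_group = dplyr::if_else(.data$enroll_age + 10L >= 85L, "ge85", "75to84"),
      Y = as.integer(.data$event == "cancer" & .data$year == .data$censor_year),
      D = as.integer(.data$event == "death" & .data$year == .data$censor_year)
    ) %>%
    dplyr::select(
      "person_id", "year", "zip", dplyr::all_of(window_names()),
      dplyr::any_of(c("pm25", "no2")),
      "sex", "race", "medicaid", "age_group", dplyr::all_of(cov_cols),
      "Y", "D"
    )
}

#' Restrict person-years to low exposure levels
#'
#' Keeps a person-year only if all three lag windows of the named
#' pollutant lie strictly below the threshold (the "all below" rule used
#' for low-level and below-guideline analyses). The other pollutant is
#' not filtered on.
#'
#' @param person_years Person-year table from [assemble_person_years()].
#' @param pollutant `"pm25"` or `"no2"`.
#' @param threshold Concentration threshold (ug/m3 for PM2.5, ppb for
#'   NO2). `Inf` is a no-op.
#' @return Filtered person-year tibble.
#' @export
restrict_by_exposure <- function(person_years, pollutant, threshold) {
  if (!pollutant %in% c("pm25", "no2")) {
    abort(paste0("unknown pollutant: ", pollutant))
  }
  cols <- window_names(pollutant)
  keep <- person_years[[cols[1]]] < threshold &
    person_years[[cols[2]]] < threshold &
    person_years[[cols[3]]] < threshold
  person_years[keep, , drop = FALSE]
}
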