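# Distributed-lag moving-average exposure windows.
#
# Exposure enters the analysis as three moving averages per pollutant,
# indexed to a person-year t: lag 0-2 = mean over {t, t-1, t-2},
# lag 3-5 = mean over {t-3, t-4, t-5}, lag 6-10 = mean over {t-6 .. t-10}.
# A person-year therefore needs 11 consecutive years of exposure history.

# Accept either the long (zip, year, pollutant, conc) or the wide
# (zip, year, pm25, no2) exposure layout and return the wide layout.
normalize_exposures <- function(zip_exposures) {
  if (all(c("pollutant", "conc") %in% names(zip_exposures))) {
    zip_exposures <- tidyr::pivot_wider(
      zip_exposures,
      names_from = "pollutant", values_from = "conc"
    )
  }
  missing <- setdiff(c("zip", "year", "pm25", "no2"), names(zip_exposures))
  if (length(missing) > 0) {
    abort(paste0(
      "exposure table lacks column(s): ", paste(missing, collapse = ", ")
    ))
  }
  dplyr::arrange(tibble::as_tibble(zip_exposures), .data$zip, .data$year)
}

#' Lag-window exposure table for every ZIP-year
#'
#' Computes, for each ZIP and calendar year, the three moving-average
#' exposure windows (lag 0-2, lag 3-5, lag 6-10 years) for PM2.5 and NO2.
#' Years without a complete 11-year history (the first ten years of each
#' ZIP's series) carry `NA` windows. The current-year concentrations are
#' kept alongside the windows.
#'
#' @param zip_exposures Exposure table, either long
#'   (`zip`, `year`, `pollutant`, `conc`) or wide (`zip`, `year`, `pm25`,
#'   `no2`). Years must be consecutive within each ZIP.
#' @return Tibble with columns `zip`, `year`, `pm25`, `no2` and the six
#'   window columns named as in [window_names()].
#' @export
zip_lag_windows <- function(zip_exposures) {
  wide <- normalize_exposures(zip_exposures)
  gaps <- wide %>%
    dplyr::summarise(
      ok = all(diff(.data$year) == 1), .by = "zip"
    )
  if (!all(gaps$ok)) {
    abort(paste0(
      "exposure years are not consecutive for zip(s): ",
      paste(utils::head(gaps$zip[!gaps$ok], 5), collapse = ", ")
    ))
  }
  roll <- function(x, from, to) {
    acc <- 0
    for (k in from:to) acc <- acc + dplyr::lag(x, k)
    acc / (to - from + 1)
  }
  wide %>%
    dplyr::mutate(
      pm25_lag02 = roll(.data$pm25, 0, 2),
      pm25_lag35 = roll(.data$pm25, 3, 5),
      pm25_lag610 = roll(.data$pm25, 6, 10),
      no2_lag02 = roll(.data$no2, 0, 2),
      no2_lag35 = roll(.data$no2, 3, 5),
      no2_lag610 = roll(.data$no2, 6, 10),
      .by = "zip"
    )
}

#' Lag-window exposures for one person-year
#'
#' Returns the six moving-average exposures for a single person at a given
#' index year, using the ZIP of residence in each lagged year (the current
#' ZIP when no residence history is supplied). Any missing ZIP-year
#' exposure is an error: windows are never silently imputed.
#'
#' @param zip_exposures Exposure table (long or wide; see
#'   [zip_lag_windows()]).
#' @param person A one-row data frame (or list) with at least `zip`; with a
#'   residence history also `person_id`.
#' @param year Index calendar year.
#' @param residences Optional long residence history
#'   (`person_id`, `year`, `zip`).
#' @return Named numeric vector of length six (see [window_names()]).
#' @export
build_lag_exposures <- function(zip_exposures, person, year, residences = NULL) {
  wide <- normalize_exposures(zip_exposures)
  lag_years <- year - (0:10)
  if (is.null(residences)) {
    zips <- rep(person$zip, 11L)
  } else {
    res <- residences[residences$person_id == person$person_id, , drop = FALSE]
    zips <- res$zip[match(lag_years, res$year)]
    if (anyNA(zips)) {
      abort(paste0(
        "no residence record for person ", person$person_id,
        " in year(s) ", paste(lag_years[is.na(zips)], collapse = ", ")
      ))
    }
  }
  idx <- match(paste(zips, lag_years), paste(wide$zip, wide$year))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    abort(paste0(
      "missing exposure for zip-year(s): ",
      paste(paste0(zips[bad], ":", lag_years[bad]), collapse = ", ")
    ))
  }
  win <- function(v, pos) mean(v[idx[pos]])
  out <- c(
    pm25_lag02 = win(wide$pm25, 1:3),
    pm25_lag35 = win(wide$pm25, 4:6),
    pm25_lag610 = win(wide$pm25, 7:11),
    no2_lag02 = win(wide$no2, 1:3),
    no2_lag35 = win(wide$no2, 4:6),
    no2_lag610 = win(wide$no2, 7:11)
  )
  out
}
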