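# Inclusion with the 10-year cancer-free run-in, censoring, and
# person-year assembly.

constant_exposures <- function(zips = "z00001", years = 1990:2016,
                               pm25 = 9, no2 = 15) {
  tab <- tidyr::crossing(zip = zips, year = years)
  tab$pm25 <- pm25
  tab$no2 <- no2
  tab
}

constant_covars <- function(zips = "z00001", years = 1990:2016) {
  tab <- tidyr::crossing(zip = zips, year = years)
  tab$adi <- 0.5
  tab$mean_bmi <- -0.2
  tab$pop_density <- 0
  tab
}

make_persons <- function(...) {
  defaults <- tibble::tibble(
    person_id = character(), sex = character(), race = character(),
    medicaid = integer(), enroll_age = integer(), enroll_year = integer(),
    zip = character(), death_year = integer(), cancer_year = integer()
  )
  rows <- tibble::tibble(...)
  for (nm in setdiff(names(defaults), names(rows))) {
    rows[[nm]] <- switch(nm,
      sex = "female", race = "white", medicaid = 0L, enroll_age = 67L,
      zip = "z00001", death_year = NA_integer_, cancer_year = NA_integer_
    )
  }
  rows
}

test_that("the run-in inclusion rule and censoring follow the stated criteria", {
  persons <- make_persons(
    person_id = c("a", "b", "c", "d", "e"),
    enroll_year = c(2000L, 2000L, 2008L, 2001L, 2000L),
    cancer_year = c(2007L, 2013L, NA, NA, NA),
    death_year = c(NA, NA, NA, 2009L, NA)
  )
  out <- apply_inclusion_and_censor(persons, study_end = 2016)
  expect_setequal(out$included$person_id, c("b", "e"))
  expect_equal(
    out$exclusions$reason[match(c("a", "c", "d"), out$exclusions$person_id)],
    c("early_cancer", "insufficient_followup", "early_death")
  )
  b <- out$included[out$included$person_id == "b", ]
  expect_equal(b$followup_start, 2010L)
  expect_equal(b$censor_year, 2013L)
  expect_equal(b$event, "cancer")
  e <- out$included[out$included$person_id == "e", ]
  expect_equal(e$censor_year, 2016L)
  expect_equal(e$event, "admin")
})

test_that("a continuous-enrollment flag excludes before any other rule", {
  persons <- make_persons(
    person_id = c("a", "b"),
    enroll_year = c(2000L, 2000L),
    cancer_year = c(2005L, NA)
  )
  persons$eligible <- c(0L, 1L)
  out <- apply_inclusion_and_censor(persons, 2016)
  expect_equal(out$exclusions$reason, "not_continuously_enrolled")
  expect_equal(out$included$person_id, "b")
})

test_that("person-year rows carry the event in the final year only", {
  persons <- make_persons(
    person_id = c("diag", "died", "admin"),
    enroll_year = 2000L,
    cancer_year = c(2012L, NA, NA),
    death_year = c(NA, 2011L, NA)
  )
  out <- apply_inclusion_and_censor(persons, 2016)
  py <- assemble_person_years(
    out$included, constant_exposures(), constant_covars()
  )
  d <- py[py$person_id == "diag", ]
  expect_equal(d$year, 2010:2012)
  expect_equal(d$Y, c(0L, 0L, 1L))
  expect_equal(d$D, c(0L, 0L, 0L))
  dd <- py[py$person_id == "died", ]
  expect_equal(dd$year, 2010:2011)
  expect_equal(dd$Y, c(0L, 0L))
  expect_equal(dd$D, c(0L, 1L))
  aa <- py[py$person_id == "admin", ]
  expect_equal(sum(aa$Y) + sum(aa$D), 0L)
  expect_equal(max(aa$year), 2016L)
  # constant exposure series: every window equals the constant
  expect_true(all(py$pm25_lag02 == 9 & py$pm25_lag610 == 9))
  expect_true(all(py$no2_lag35 == 15))
  # a diagnosis in the first follow-up year still contributes one row
  one <- make_persons(
    person_id = "f", enroll_year = 2000L, cancer_year = 2010L
  )
  out1 <- apply_inclusion_and_censor(one, 2016)
  py1 <- assemble_person_years(out1$included, constant_exposures(), constant_covars())
  expect_equal(nrow(py1), 1L)
  expect_equal(py1$Y, 1L)
})

test_that("observation years are conserved between included and excluded", {
  withr::with_seed(8, {
    n <- 300
    persons <- make_persons(
      person_id = sprintf("p%03d", 1:n),
      enroll_year = sample(2000:2010, n, replace = TRUE),
      cancer_year = NA_integer_,
      death_year = NA_integer_
    )
    has_cancer <- stats::runif(n) < 0.3
    persons$cancer_year[has_cancer] <-
      persons$enroll_year[has_cancer] + sample(0:16, sum(has_cancer), TRUE)
    has_death <- stats::runif(n) < 0.3 & !has_cancer
    persons$death_year[has_death] <-
      persons$enroll_year[has_death] + sample(0:16, sum(has_death), TRUE)
    persons$cancer_year[persons$cancer_year > 2016] <- NA
    persons$death_year[persons$death_year > 2016] <- NA
  })
  out <- apply_inclusion_and_censor(persons, 2016)
  total_obs <- sum(
    pmin(persons$cancer_year, persons$death_year, 2016, na.rm = TRUE) -
      persons$enroll_year + 1
  )
  included_obs <- sum(out$included$censor_year - out$included$enroll_year + 1)
  expect_equal(included_obs + sum(out$exclusions$obs_years), total_obs)
  expect_equal(nrow(out$included) + nrow(out$exclusions), n)

  # every included person contributes >= 1 person-year; none past the event
  if (nrow(out$included) > 0) {
    py <- assemble_person_years(
      out$included,
      constant_exposures(years = 1990:2016),
      constant_covars(years = 1990:2016)
    )
    counts <- table(py$person_id)
    expect_true(all(counts >= 1))
    expect_equal(
      sum(py$Y),
      sum(!is.na(out$included$cancer_year) &
        out$included$event == "cancer")
    )
    last <- tapply(py$year, py$person_id, max)
    expect_equal(
      as.vector(last[out$included$person_id]),
      as.vector(out$included$censor_year)
    )
  }
})

test_that("missing exposures or covariates abort assembly with context", {
  persons <- make_persons(person_id = "a", enroll_year = 2000L)
  out <- apply_inclusion_and_censor(persons, 2016)
  short <- constant_exposures(years = 2001:2016) # lag 6-10 incomplete
  expect_error(
    assemble_person_years(out$included, short, constant_covars()),
    "consecutive|lag exposures"
  )
  expect_error(
    assemble_person_years(
      out$included, constant_exposures(),
      constant_covars(years = 2014:2016)
    ),
    "covariates unavailable"
  )
})

test_that("exposure restriction keeps only person-years with all windows strictly below", {
  py <- synthetic_py(3, x = c(9.9, 9.9, 5))
  py$pm25_lag02 <- c(9.9, 9.9, 5)
  py$pm25_lag35 <- c(9.9, 10.0, 5)
  py$pm25_lag610 <- c(9.9, 9.9, 5)
  kept <- restrict_by_exposure(py, "pm25", 10)
  expect_equal(kept$person_id, py$person_id[c(1, 3)]) # 10.0 is not below 10
  expect_identical(restrict_by_exposure(py, "pm25", Inf), py)
  # the other pollutant is not filtered on
  py$no2_lag02 <- 1000
  expect_equal(nrow(restrict_by_exposure(py, "pm25", 10)), 2L)
  expect_error(restrict_by_exposure(py, "ozone", 10), "unknown pollutant")
})

test_that("mobility routes person-years through the residence history", {
  persons <- make_persons(
    person_id = "m", enroll_year = 2000L, zip = "z00002"
  )
  out <- apply_inclusion_and_censor(persons, 2013)
  exposures <- dplyr::bind_rows(
    constant_exposures("z00001", pm25 = 2, no2 = 1),
    constant_exposures("z00002", pm25 = 13, no2 = 1)
  )
  covars <- dplyr::bind_rows(
    constant_covars("z00001"), constant_covars("z00002")
  )
  res <- tibble::tibble(
    person_id = "m", year = 2000:2013,
    zip = c(rep("z00001", 12), rep("z00002", 2)) # moves in 2012
  )
  py <- assemble_person_years(out$included, exposures, covars, residences = res)
  expect_equal(py$year, 2010:2013)
  expect_equal(py$pm25_lag02[py$year == 2013], mean(c(13, 13, 2)))
  expect_equal(py$pm25_lag610[py$year == 2013], 2)
  expect_equal(py$pm25_lag02[py$year == 2010], 2)
})
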