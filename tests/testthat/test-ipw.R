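# Stage 1: exposure model, death models, stabilized weights, balance.

test_that("the null exposure model is the sample mean", {
  withr::with_seed(1, {
    py <- synthetic_py(500, x = stats::rnorm(500, 10, 2))
  })
  spec <- design_spec("pm25_lag02", gbm_params = list(n_trees = 0))
  m <- fit_exposure_model(py, spec)
  expect_equal(m$fitted, rep(mean(py$pm25_lag02), 500))
  expect_equal(m$residuals, py$pm25_lag02 - mean(py$pm25_lag02))
})

test_that("an exposure independent of the confounders has mean-like predictions", {
  withr::with_seed(2, {
    py <- synthetic_py(20000, x = stats::rnorm(20000, 10, 2))
  })
  spec <- design_spec("pm25_lag02", gbm_params = list(n_trees = 50, learning_rate = 0.1))
  m <- fit_exposure_model(py, spec)
  expect_lt(var(m$fitted) / var(py$pm25_lag02), 0.15)
  expect_gt(stats::cor(m$residuals, py$pm25_lag02 - mean(py$pm25_lag02)), 0.9)
})

test_that("a deterministic confounder relationship is captured by the boosting", {
  withr::with_seed(3, {
    z <- stats::rnorm(20000)
    py <- synthetic_py(20000, x = 10 + 2 * z)
    py$adi <- z
  })
  spec <- design_spec("pm25_lag02",
    gbm_params = list(n_trees = 300, learning_rate = 0.1)
  )
  m <- fit_exposure_model(py, spec)
  expect_lt(var(m$residuals) / var(py$pm25_lag02), 0.05)
  expect_gt(m$r_squared, 0.95)
  expect_error(
    fit_exposure_model(synthetic_py(100, x = rep(5, 100)), spec),
    "constant"
  )
})

test_that("death independent of everything gives a unit competing-risk factor", {
  withr::with_seed(4, {
    n <- 20000
    py <- synthetic_py(n,
      x = stats::rnorm(n, 10, 2),
      d = stats::rbinom(n, 1, 0.1)
    )
  })
  for (loss in c("bernoulli", "gaussian_literal")) {
    spec <- design_spec("pm25_lag02",
      gbm_params = list(n_trees = 100, learning_rate = 0.1, loss = loss)
    )
    dm <- fit_death_models(py, spec)
    expect_lt(abs(mean(dm$surv_num) - 0.9), 0.02)
    expect_lt(abs(mean(dm$surv_den) - 0.9), 0.02)
    factor <- dm$surv_num / dm$surv_den
    expect_lt(abs(mean(factor) - 1), 0.02)
  }
})

test_that("death depending only on the exposure still cancels in the factor", {
  withr::with_seed(5, {
    n <- 20000
    x <- stats::rnorm(n, 10, 2)
    d <- stats::rbinom(n, 1, stats::plogis(-3 + 0.15 * (x - 10)))
    py <- synthetic_py(n, x = x, d = d)
  })
  spec <- design_spec("pm25_lag02",
    gbm_params = list(n_trees = 150, learning_rate = 0.1)
  )
  dm <- fit_death_models(py, spec)
  factor <- dm$surv_num / dm$surv_den
  expect_lt(abs(mean(factor) - 1), 0.02)
  expect_lt(stats::sd(factor), 0.1)
})

test_that("a confounder-driven death process up-weights death-prone survivors", {
  # two strata: z = 1 dies with probability 0.3, z = 0 with 0.05;
  # exposure independent of z, so the exact factor is
  # P(D=0) aggregated over x alone divided by the per-stratum rate
  withr::with_seed(6, {
    n <- 40000
    z <- stats::rbinom(n, 1, 0.5)
    x <- stats::rnorm(n, 10, 2)
    d <- stats::rbinom(n, 1, ifelse(z == 1, 0.3, 0.05))
    py <- synthetic_py(n, x = x, d = d)
    py$adi <- z
  })
  spec <- design_spec("pm25_lag02",
    confounders = "adi",
    gbm_params = list(n_trees = 200, learning_rate = 0.1)
  )
  dm <- fit_death_models(py, spec)
  factor <- dm$surv_num / dm$surv_den
  marg <- 1 - mean(d)
  expect_lt(abs(mean(factor[z == 1]) - marg / 0.7), 0.05)
  expect_lt(abs(mean(factor[z == 0]) - marg / 0.95), 0.05)
  expect_gt(mean(factor[z == 1]), mean(factor[z == 0]))
})

test_that("no deaths warns and degenerates the factor to one", {
  py <- synthetic_py(200, x = stats::rnorm(200))
  spec <- design_spec("pm25_lag02", gbm_params = list(n_trees = 10))
  expect_warning(dm <- fit_death_models(py, spec), "no deaths")
  expect_equal(dm$surv_num, rep(1, 200))
  expect_equal(dm$surv_den, rep(1, 200))
  py$D <- 1L
  expect_error(fit_death_models(py, spec), "every person-year")
})

test_that("two-strata normal weights match the closed-form density ratio", {
  # z binary; x | z ~ N(mu_z, 1); no deaths. The true stabilized weight
  # is the normal mixture density at x over the conditional normal
  # density at x - mu_z.
  withr::with_seed(7, {
    n <- 50000
    z <- stats::rbinom(n, 1, 0.5)
    mu <- ifelse(z == 1, 11, 10)
    x <- stats::rnorm(n, mu, 1)
    py <- synthetic_py(n, x = x)
    py$adi <- z
  })
  spec <- design_spec("pm25_lag02",
    confounders = "adi",
    gbm_params = list(n_trees = 300, learning_rate = 0.1),
    truncation = NULL
  )
  ws <- suppressWarnings(stabilized_weights(py, spec))
  p1 <- mean(z)
  oracle <- (p1 * stats::dnorm(x, 11, 1) + (1 - p1) * stats::dnorm(x, 10, 1)) /
    stats::dnorm(x, mu, 1)
  expect_gt(stats::cor(ws$weights$sw, oracle, method = "spearman"), 0.99)
  expect_lt(abs(mean(ws$weights$sw) - 1), 0.05)
})

test_that("weight components multiply exactly and truncation caps at the percentiles", {
  py <- shared_confounded_cohort()
  spec <- design_spec("pm25_lag02", gbm_params = study_gbm, seed = 11)
  ws <- stabilized_weights(py, spec)
  w <- ws$weights
  expect_identical(
    w$sw_raw, w$k_num / w$k_den * w$surv_num / w$surv_den
  )
  expect_equal(max(w$sw), unname(stats::quantile(w$sw_raw, 0.99)))
  expect_equal(min(w$sw), unname(stats::quantile(w$sw_raw, 0.01)))
  expect_true(all(w$sw > 0 & is.finite(w$sw)))
  expect_lte(ws$diagnostics$ess, ws$diagnostics$n)
  expect_lte(mean(w$sw != w$sw_raw), 0.021)
  # determinism under a fixed seed
  ws2 <- stabilized_weights(py, spec)
  expect_identical(ws$weights, ws2$weights)
})

test_that("weighting reduces the exposure-confounder association it targets", {
  py <- shared_confounded_cohort()
  spec <- design_spec("pm25_lag02", gbm_params = study_gbm, seed = 11)
  ws <- stabilized_weights(py, spec)
  bal <- ws$diagnostics$balance
  adi <- bal[bal$covariate == "adi", ]
  expect_gt(abs(adi$unweighted), 0.1) # confounding is real before weighting
  expect_lt(abs(adi$weighted), abs(adi$unweighted))
})

test_that("unit weights reproduce unweighted associations; degenerate covariates flag", {
  py <- synthetic_py(2000, x = stats::rnorm(2000, 10, 2), seed = 12)
  py$flat <- 1
  bal <- balance_diagnostics(
    py, rep(1, 2000),
    target_exposure = "pm25_lag02",
    confounders = c("adi", "mean_bmi", "flat", "race")
  )
  adi <- bal[bal$covariate == "adi", ]
  expect_equal(adi$weighted, adi$unweighted)
  expect_equal(
    adi$unweighted,
    stats::cor(py$pm25_lag02, py$adi)
  )
  flat <- bal[bal$covariate == "flat", ]
  expect_true(flat$degenerate)
  expect_equal(flat$weighted, 0)
})

test_that("a well-specified null design keeps weights near one", {
  withr::with_seed(13, {
    n <- 30000
    py <- synthetic_py(n, x = stats::rnorm(n, 10, 2),
      d = stats::rbinom(n, 1, 0.08))
  })
  spec <- design_spec("pm25_lag02",
    confounders = c("adi", "mean_bmi", "pop_density"),
    gbm_params = list(n_trees = 100, learning_rate = 0.1)
  )
  ws <- stabilized_weights(py, spec)
  expect_lt(abs(ws$diagnostics$mean_weight_raw - 1), 0.1)
  expect_lt(stats::quantile(abs(ws$weights$sw - 1), 0.95), 0.35)
})

test_that("design specifications are validated", {
  expect_error(design_spec("pm25"), "target_exposure")
  expect_error(
    design_spec("pm25_lag02", confounders = c("pm25_lag02", "adi")),
    "must not appear"
  )
  expect_error(design_spec("pm25_lag02", truncation = c(99, 1)), "percentiles")
  expect_error(
    design_spec("pm25_lag02", gbm_params = list(loss = "poisson")),
    "loss"
  )
})
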