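# Stage 2: the IPW-weighted linear probability model
#
#   E(Y_i = 1 | x_i) = beta0 + beta1 * x_i
#
# fit by weighted least squares with the stabilized weights, so beta1 is
# the additive risk difference (absolute change in annual diagnosis
# probability per unit exposure). The coefficient is converted to an
# annual attributable case count via beta1 * N / duration.

#' Fit the IPW-weighted linear probability model
#'
#' Weighted least squares of the diagnosis indicator on the single
#' target exposure. The default standard error is the
#' heteroskedasticity-robust sandwich clustered on beneficiary (a person
#' contributes correlated person-years); a nonparametric cluster
#' bootstrap (resampling persons) is available as an alternative.
#' Stage-1 estimation uncertainty is not propagated.
#'
#' @param person_years Person-year table.
#' @param weights An `ipw_weight_set` from [stabilized_weights()], or a
#'   numeric vector of weights aligned with `person_years`.
#' @param target_exposure Window column to regress on; defaults to the
#'   weight set's target.
#' @param variance `"cluster_robust"` (default) or
#'   `"cluster_bootstrap"`.
#' @param n_boot Bootstrap replicates when `variance =
#'   "cluster_bootstrap"`.
#' @return Object of class `additive_fit` with `beta0`, `beta1`,
#'   `se_beta1`, `ci95`, `n_person_years_analysis`, `n_events`,
#'   `variance_method`, `target_exposure`.
#' @export
weighted_lpm <- function(person_years, weights, target_exposure = NULL,
                         variance = c("cluster_robust", "cluster_bootstrap"),
                         n_boot = 200) {
  variance <- match.arg(variance)
  if (inherits(weights, "ipw_weight_set")) {
    target_exposure <- target_exposure %||% weights$spec$target_exposure
    w <- weights$weights$sw
    if (nrow(weights$weights) != nrow(person_years) ||
      !identical(weights$weights$person_id, person_years$person_id)) {
      abort("weights are not aligned 1:1 with the person-year table")
    }
  } else {
    w <- as.numeric(weights)
    if (length(w) != nrow(person_years)) {
      abort("weights are not aligned 1:1 with the person-year table")
    }
    if (is.null(target_exposure)) abort("target_exposure must be given")
  }
  x <- person_years[[target_exposure]]
  y <- person_years$Y
  wx_var <- weighted_cor(x, x, w) # degenerate attr when variance is zero
  if (isTRUE(attr(wx_var, "degenerate"))) {
    abort("target exposure has zero weighted variance")
  }

  dat <- data.frame(y = y, x = x, .w = w)
  fit <- lm(y ~ x, data = dat, weights = .w)
  beta <- coef(fit)
  degenerate_se <- FALSE
  if (all(y == 0)) {
    warn("all outcomes are zero; slope is 0 with a degenerate SE")
    se <- 0
    degenerate_se <- TRUE
  } else if (variance == "cluster_robust") {
    vc <- sandwich::vcovCL(fit,
      cluster = person_years$person_id, type = "HC0"
    )
    se <- sqrt(vc["x", "x"])
  } else {
    ids <- unique(person_years$person_id)
    idx_by_id <- split(seq_len(nrow(person_years)), person_years$person_id)
    boots <- vapply(seq_len(n_boot), function(b) {
      take <- unlist(idx_by_id[sample(length(ids), replace = TRUE)],
        use.names = FALSE
      )
      xb <- x[take]
      yb <- y[take]
      wb <- w[take]
      xm <- weighted.mean(xb, wb)
      sum(wb * (xb - xm) * yb) / sum(wb * (xb - xm)^2)
    }, numeric(1))
    se <- sd(boots)
  }
  ci <- unname(beta["x"] + c(-1.96, 1.96) * se)

  structure(
    list(
      beta0 = unname(beta["(Intercept)"]),
      beta1 = unname(beta["x"]),
      se_beta1 = se,
      ci95 = ci,
      n_person_years_analysis = nrow(person_years),
      n_events = sum(y),
      ess = sum(w)^2 / sum(w^2),
      variance_method = variance,
      degenerate_se = degenerate_se,
      target_exposure = target_exposure
    ),
    class = "additive_fit"
  )
}

#' @export
print.additive_fit <- function(x, ...) {
  cat(sprintf(
    "Additive risk model for %s (%s SE)\n", x$target_exposure,
    x$variance_method
  ))
  cat(sprintf(
    "  beta1 = %.6g per unit (95%% CI %.6g, %.6g); beta0 = %.6g\n",
    x$beta1, x$ci95[1], x$ci95[2], x$beta0
  ))
  cat(sprintf(
    "  %d person-years, %d events\n",
    x$n_person_years_analysis, x$n_events
  ))
  invisible(x)
}

#' @rdname weighted_lpm
#' @param x An `additive_fit`.
#' @param ... Unused.
#' @export
tidy.additive_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$target_exposure),
    estimate = c(x$beta0, x$beta1),
    std.error = c(NA_real_, x$se_beta1),
    conf.low = c(NA_real_, x$ci95[1]),
    conf.high = c(NA_real_, x$ci95[2])
  )
}

#' @rdname weighted_lpm
#' @export
glance.additive_fit <- function(x, ...) {
  tibble::tibble(
    n_person_years = x$n_person_years_analysis,
    n_events = x$n_events,
    ess = x$ess,
    variance_method = x$variance_method
  )
}

#' Convert a risk difference to annual attributable cases
#'
#' `annual_cases = beta1 * N / duration`, where `N` is the person-year
#' denominator and `duration` the study span in years (17 for a
#' 2000-2016 study). The confidence bounds are the same linear transform
#' of the coefficient's bounds. Values are kept at full precision;
#' round with [round_cases()] at report time.
#'
#' @param fit An `additive_fit`.
#' @param N Person-year denominator. The convention of the attributable
#'   count includes the person-years of beneficiaries excluded during
#'   the 10-year run-in; pass the analysis table's person-years instead
#'   to restrict the denominator.
#' @param duration Study duration in years.
#' @return Object of class `case_estimate` with `annual_cases`, `ci95`,
#'   `N_denominator`, `duration`, plus the originating coefficient and
#'   target.
#' @export
annual_cases <- function(fit, N, duration = 17) {
  if (N <= 0) abort("N must be positive")
  if (duration <= 0) abort("duration must be positive")
  scale <- N / duration
  structure(
    list(
      annual_cases = fit$beta1 * scale,
      ci95 = fit$ci95 * scale,
      N_denominator = N,
      duration = duration,
      beta1 = fit$beta1,
      target_exposure = fit$target_exposure
    ),
    class = "case_estimate"
  )
}

#' @export
print.case_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: %d annual cases per unit (95%% CI %d, %d); N = %s person-years over %g years\n",
    x$target_exposure %||% "exposure",
    round_cases(x$annual_cases), round_cases(x$ci95[1]),
    round_cases(x$ci95[2]),
    format(x$N_denominator, big.mark = ","), x$duration
  ))
  invisible(x)
}

#' @rdname annual_cases
#' @param x A `case_estimate`.
#' @param ... Unused.
#' @export
tidy.case_estimate <- function(x, ...) {
  tibble::tibble(
    target_exposure = x$target_exposure %||% NA_character_,
    annual_cases = x$annual_cases,
    conf.low = x$ci95[1],
    conf.high = x$ci95[2],
    N = x$N_denominator,
    duration = x$duration
  )
}

#' Combine the three lag windows of one pollutant
#'
#' Because the per-window estimates are mutually adjusted (each window's
#' model treats the other five as confounders) and additive, their
#' attributable-case point estimates can be summed to an overall
#' 10-year-window total. No confidence interval is combined.
#'
#' @param case_estimates List of three `case_estimate` objects for the
#'   same pollutant and cohort, one per window (or a bare numeric
#'   length-3 vector of annual case counts).
#' @return One-row tibble with `pollutant` (when known) and
#'   `annual_cases_combined`.
#' @export
combine_windows <- function(case_estimates) {
  if (is.numeric(case_estimates)) {
    if (length(case_estimates) != 3) {
      abort("exactly three window estimates are required")
    }
    return(tibble::tibble(
      pollutant = NA_character_,
      annual_cases_combined = sum(case_estimates)
    ))
  }
  if (length(case_estimates) != 3 ||
    !all(vapply(case_estimates, inherits, logical(1), "case_estimate"))) {
    abort("exactly three case_estimate objects are required")
  }
  targets <- vapply(case_estimates, function(e) e$target_exposure, character(1))
  pollutants <- vapply(strsplit(targets, "_"), `[[`, character(1), 1)
  windows <- vapply(strsplit(targets, "_"), `[[`, character(1), 2)
  if (length(unique(pollutants)) != 1) {
    abort("window estimates mix pollutants")
  }
  if (length(unique(windows)) != 3) {
    abort("window estimates must cover three distinct windows")
  }
  Ns <- vapply(case_estimates, function(e) e$N_denominator, numeric(1))
  if (length(unique(Ns)) != 1) {
    abort("window estimates come from different cohorts (N differs)")
  }
  tibble::tibble(
    pollutant = pollutants[1],
    annual_cases_combined = sum(
      vapply(case_estimates, function(e) e$annual_cases, numeric(1))
    )
  )
}
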