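# Restriction and subgroup analyses: the full two-stage pipeline
# (weights re-estimated from scratch, then the weighted LPM) re-run on
# filtered strata — low-exposure restrictions and subgroup splits.

#' Describe a restriction or subgroup analysis
#'
#' @param type `"main"`, `"low_level"` (defaults: PM2.5 < 10 ug/m3,
#'   NO2 < 20 ppb), `"below_aqg"` (WHO guideline levels: PM2.5 < 5,
#'   NO2 < 10) or `"subgroup"`.
#' @param thresholds Named numeric `c(pm25 = , no2 = )` overriding the
#'   restriction defaults.
#' @param both_pollutants Restrict on both pollutants' windows rather
#'   than only the analyzed pollutant's.
#' @param subgroup_axis Column to stratify on (`subgroup` type):
#'   a categorical person-level column (`age_group`, `sex`, `race`,
#'   `medicaid`) or a continuous community covariate.
#' @param subgroup_rule For continuous axes, `"quartiles"` (lower vs
#'   upper quartile strata); ignored for categorical axes.
#' @return Object of class `ipw_analysis_plan`.
#' @export
analysis_plan <- function(type = c("main", "low_level", "below_aqg", "subgroup"),
                          thresholds = NULL,
                          both_pollutants = FALSE,
                          subgroup_axis = NULL,
                          subgroup_rule = "quartiles") {
  type <- match.arg(type)
  defaults <- switch(type,
    low_level = c(pm25 = 10, no2 = 20),
    below_aqg = c(pm25 = 5, no2 = 10),
    NULL
  )
  if (!is.null(thresholds)) {
    if (is.null(names(thresholds)) ||
      !all(names(thresholds) %in% c("pm25", "no2")) ||
      any(thresholds <= 0)) {
      abort("thresholds must be positive and named pm25/no2")
    }
    defaults[names(thresholds)] <- thresholds
  }
  if (type == "subgroup" && is.null(subgroup_axis)) {
    abort("subgroup plans need a subgroup_axis")
  }
  structure(
    list(
      type = type, thresholds = defaults, both_pollutants = both_pollutants,
      subgroup_axis = subgroup_axis, subgroup_rule = subgroup_rule
    ),
    class = "ipw_analysis_plan"
  )
}

# one full two-stage run on a person-year subset; emits a one-row fits
# tibble (NA estimates with a reason code when the stratum is unusable)
fit_one_analysis <- function(person_years, target_exposure, analysis_label,
                             subgroup_label = NA_character_,
                             design_args = list(), N_total = NULL,
                             duration = 17,
                             min_person_years = 5000, min_events = 20,
                             variance = "cluster_robust") {
  base <- tibble::tibble(
    analysis = analysis_label,
    subgroup = subgroup_label,
    target_exposure = target_exposure,
    n_person_years = nrow(person_years),
    n_events = sum(person_years$Y),
    beta0 = NA_real_, beta1 = NA_real_, se_beta1 = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_,
    annual_cases = NA_real_, cases_ci_low = NA_real_,
    cases_ci_high = NA_real_,
    N_denominator = NA_real_, duration = duration,
    mean_weight = NA_real_, ess_fraction = NA_real_,
    seed = design_args$seed %||% 1L,
    reason = NA_character_
  )
  if (nrow(person_years) == 0 || base$n_events == 0) {
    base$reason <- "no_events"
    return(base)
  }
  if (nrow(person_years) < min_person_years || base$n_events < min_events) {
    base$reason <- "stratum_too_small"
    return(base)
  }
  spec <- do.call(design_spec, c(list(target_exposure = target_exposure), design_args))
  ws <- stabilized_weights(person_years, spec)
  fit <- weighted_lpm(person_years, ws, variance = variance)
  N <- N_total %||% nrow(person_years)
  cases <- annual_cases(fit, N = N, duration = duration)
  base %>%
    dplyr::mutate(
      beta0 = fit$beta0, beta1 = fit$beta1, se_beta1 = fit$se_beta1,
      ci_low = fit$ci95[1], ci_high = fit$ci95[2],
      annual_cases = cases$annual_cases,
      cases_ci_low = cases$ci95[1], cases_ci_high = cases$ci95[2],
      N_denominator = N,
      mean_weight = ws$diagnostics$mean_weight,
      ess_fraction = ws$diagnostics$ess_fraction
    )
}

#' Run a restricted (or main) analysis for one exposure window
#'
#' Applies the plan's exposure restriction — all three windows of the
#' analyzed pollutant strictly below the threshold (optionally both
#' pollutants) — then re-runs stage 1 and stage 2 from scratch on the
#' subset. Weights are always re-estimated within the subset. Unusable
#' strata (empty, event-free, or below the minimum-size guards) yield an
#' NA row with a reason code rather than an error.
#'
#' @param person_years Person-year table.
#' @param plan An [analysis_plan()] of type `main`, `low_level` or
#'   `below_aqg`.
#' @param target_exposure Window column being analyzed.
#' @param design_args List of arguments passed to [design_spec()]
#'   (confounders, gbm_params, kde_params, truncation, seed).
#' @param N_total Person-year denominator for the case conversion
#'   (defaults to the subset's analysis person-years).
#' @param duration Study duration in years.
#' @param min_person_years,min_events Minimum stratum size guards.
#' @param variance Variance method passed to [weighted_lpm()].
#' @return One-row fits tibble.
#' @export
run_restricted <- function(person_years, plan, target_exposure,
                           design_args = list(), N_total = NULL,
                           duration = 17,
                           min_person_years = 5000, min_events = 20,
                           variance = "cluster_robust") {
  if (plan$type == "subgroup") {
    abort("use run_subgroups() for subgroup plans")
  }
  subset <- person_years
  if (plan$type %in% c("low_level", "below_aqg")) {
    pollutant <- parse_window(target_exposure)$pollutant
    pollutants <- if (plan$both_pollutants) c("pm25", "no2") else pollutant
    for (p in pollutants) {
      subset <- restrict_by_exposure(subset, p, plan$thresholds[[p]])
    }
  }
  fit_one_analysis(
    subset, target_exposure, plan$type,
    design_args = design_args, N_total = N_total, duration = duration,
    min_person_years = min_person_years, min_events = min_events,
    variance = variance
  )
}

#' Run subgroup analyses for one exposure window
#'
#' Categorical axes are split by level (an axis with fewer than two
#' observed levels is an error); continuous community covariates are
#' split into the person-years whose value lies in the lowest vs highest
#' quartile, with quartiles computed over person-years and boundaries
#' inclusive. The full two-stage pipeline runs per stratum.
#'
#' @inheritParams run_restricted
#' @param axis Column to stratify on.
#' @return Fits tibble with one row per stratum.
#' @export
run_subgroups <- function(person_years, axis, target_exposure,
                          design_args = list(), N_total = NULL,
                          duration = 17,
                          min_person_years = 5000, min_events = 20,
                          variance = "cluster_robust") {
  if (!axis %in% names(person_years)) {
    abort(paste0("subgroup axis '", axis, "' not found in the person-year table"))
  }
  v <- person_years[[axis]]
  if (is.numeric(v) && length(unique(v)) > 2) {
    qs <- quantile(v, c(0.25, 0.75), names = FALSE)
    strata <- list(
      lower_quartile = person_years[v <= qs[1], , drop = FALSE],
      upper_quartile = person_years[v >= qs[2], , drop = FALSE]
    )
  } else {
    lv <- sort(unique(as.character(v)))
    if (length(lv) < 2) {
      abort(paste0(
        "subgroup axis '", axis, "' has a single level in this cohort; ",
        "a subgroup analysis is not defined"
      ))
    }
    strata <- stats::setNames(
      lapply(lv, function(l) person_years[as.character(v) == l, , drop = FALSE]),
      lv
    )
  }
  purrr::imap(strata, function(sub, label) {
    fit_one_analysis(
      sub, target_exposure, "subgroup",
      subgroup_label = paste0(axis, ":", label),
      design_args = design_args, N_total = N_total, duration = duration,
      min_person_years = min_person_years, min_events = min_events,
      variance = variance
    )
  }) %>% dplyr::bind_rows()
}

#' Run a set of analyses over exposure windows and plans
#'
#' Loops the analyzed windows over a list of analysis plans (main,
#' restrictions, subgroups) and returns one consolidated fits table, a
#' machine-readable analogue of a per-window results table. Each
#' window's stage 1 is re-fit from scratch with the other five windows
#' among its confounders.
#'
#' @inheritParams run_restricted
#' @param targets Character vector of window columns to analyze.
#' @param plans List of [analysis_plan()]s.
#' @param seed Base seed; each (target, plan) combination derives its
#'   own seed deterministically so any row can be re-run in isolation.
#' @return Consolidated fits tibble.
#' @export
run_analysis_set <- function(person_years, targets = window_names(),
                             plans = list(analysis_plan("main")),
                             design_args = list(), N_total = NULL,
                             duration = 17, seed = 1L,
                             min_person_years = 5000, min_events = 20,
                             variance = "cluster_robust") {
  combos <- tidyr::crossing(
    target = targets,
    plan_idx = seq_along(plans)
  )
  purrr::pmap(combos, function(target, plan_idx) {
    plan <- plans[[plan_idx]]
    args <- design_args
    args$seed <- derive_seed(seed, "design") +
      match(target, window_names()) * 10L + plan_idx
    if (plan$type == "subgroup") {
      run_subgroups(
        person_years, plan$subgroup_axis, target,
        design_args = args, N_total = N_total, duration = duration,
        min_person_years = min_person_years, min_events = min_events,
        variance = variance
      )
    } else {
      run_restricted(
        person_years, plan, target,
        design_args = args, N_total = N_total, duration = duration,
        min_person_years = min_person_years, min_events = min_events,
        variance = variance
      )
    }
  }) %>% dplyr::bind_rows()
}
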