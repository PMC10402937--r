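# End-to-end orchestration: simulate (or load) -> build the person-year
# table -> design weights and fit per window and plan -> write a run
# directory. A single global seed fans out deterministically to the
# stages, so reruns of the same configuration are bit-identical.

#' Run the full two-stage pipeline
#'
#' Executes simulate/load, cohort construction, and the analysis set,
#' writing `person_years.csv`, `exclusions.csv`, `fits.csv` and a
#' configuration echo (`run_config.json`) into `out_dir`. When a
#' simulation is configured the synthetic cohort files are written too.
#'
#' @param config Either a list or a path to a YAML file with elements:
#'   `seed` (required), and one of `simulation` (arguments for
#'   [sim_config()]; `truth` sub-lists are passed to [sim_truth()]) or
#'   `input_dir` (a directory readable by [read_cohort()]);
#'   optional `study_end`, `targets` (default all six windows), `plans`
#'   (list of [analysis_plan()] argument lists; default main only),
#'   `design` ([design_spec()] arguments), `duration` (default 17),
#'   `denominator` (`"total"`, the default, counts included + excluded
#'   observation years; `"analysis"` counts analysis person-years only),
#'   `min_person_years`, `min_events`, `write_weights` (default FALSE).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `fits`, `person_years`, `exclusions`,
#'   `N_total`, `N_analysis` and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) abort("config must set a seed")
  seed <- as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    if (!is.null(sim_args$truth) && !inherits(sim_args$truth, "sim_truth")) {
      truth_args <- lapply(sim_args$truth, function(v) {
        if (is.list(v)) unlist(v) else v
      })
      sim_args$truth <- do.call(sim_truth, truth_args)
    }
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_cohort(cfg)
    write_cohort(sim, out_dir)
    persons <- sim$persons
    exposures <- sim$zip_exposures
    covars <- sim$zip_covariates
    residences <- sim$residences
    study_end <- config$study_end %||% cfg$study_end
  } else if (!is.null(config$input_dir)) {
    dat <- read_cohort(config$input_dir)
    persons <- dat$persons
    exposures <- dat$zip_exposures
    covars <- dat$zip_covariates
    residences <- dat$residences
    study_end <- config$study_end %||% max(persons$enroll_year + 10L)
  } else {
    abort("config must provide either `simulation` or `input_dir`")
  }

  cohort <- apply_inclusion_and_censor(persons, study_end)
  py <- assemble_person_years(
    cohort$included, exposures, covars,
    residences = residences
  )
  readr::write_csv(py, file.path(out_dir, "person_years.csv"))
  readr::write_csv(cohort$exclusions, file.path(out_dir, "exclusions.csv"))

  n_analysis <- nrow(py)
  # total observation years: analysis years + run-in years of included
  # persons + observation years of excluded persons
  included_obs <- sum(cohort$included$censor_year -
    cohort$included$enroll_year + 1L)
  n_total <- included_obs + sum(cohort$exclusions$obs_years)
  denominator <- config$denominator %||% "total"
  N_used <- if (denominator == "analysis") n_analysis else n_total

  plans <- if (is.null(config$plans)) {
    list(analysis_plan("main"))
  } else {
    lapply(config$plans, function(p) do.call(analysis_plan, p))
  }
  targets <- config$targets %||% window_names()

  fits <- run_analysis_set(
    py,
    targets = targets, plans = plans,
    design_args = config$design %||% list(),
    N_total = N_used,
    duration = config$duration %||% 17,
    seed = seed,
    min_person_years = config$min_person_years %||% 5000,
    min_events = config$min_events %||% 20
  )
  readr::write_csv(fits, file.path(out_dir, "fits.csv"))

  if (isTRUE(config$write_weights)) {
    for (target in targets) {
      spec <- do.call(design_spec, c(
        list(target_exposure = target),
        utils::modifyList(
          config$design %||% list(),
          list(seed = derive_seed(seed, "design") +
            match(target, window_names()) * 10L + 1L)
        )
      ))
      ws <- stabilized_weights(py, spec)
      write_weight_set(ws, out_dir, prefix = paste0("weights_", target))
    }
  }

  echo <- list(
    seed = seed,
    study_end = study_end,
    denominator = denominator,
    N_total_observation_years = n_total,
    N_analysis_person_years = n_analysis,
    n_included = nrow(cohort$included),
    n_excluded = nrow(cohort$exclusions),
    targets = targets,
    plans = lapply(plans, unclass),
    design = config$design %||% list(),
    package_version = as.character(utils::packageVersion("ipwadd"))
  )
  jsonlite::write_json(echo, file.path(out_dir, "run_config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  invisible(list(
    fits = fits, person_years = py, exclusions = cohort$exclusions,
    N_total = n_total, N_analysis = n_analysis, out_dir = out_dir
  ))
}

#' Write a weight set to disk
#'
#' Emits `<prefix>.csv` (per-person-year weights and their four
#' components) and `<prefix>_report.json` (diagnostics and the design
#' specification echo).
#'
#' @param ws An `ipw_weight_set`.
#' @param dir Output directory.
#' @param prefix File name prefix (default `"weights"`).
#' @return The CSV path, invisibly.
#' @export
write_weight_set <- function(ws, dir, prefix = "weights") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0(prefix, ".csv"))
  readr::write_csv(ws$weights, path)
  report <- list(
    diagnostics = ws$diagnostics[c(
      "n", "mean_weight", "max_weight", "ess", "ess_fraction",
      "r_squared_exposure"
    )],
    balance = ws$diagnostics$balance,
    spec = unclass(ws$spec)
  )
  jsonlite::write_json(report, file.path(dir, paste0(prefix, "_report.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
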