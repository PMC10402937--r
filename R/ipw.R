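# Stage 1: stabilized inverse-probability weights for one continuous
# exposure window with a competing risk of death.
#
# For person-year i with target exposure x_i, confounders c_i and death
# indicator D_i, the stabilized weight is
#
#   sw_i = K_num(x_i - xbar) / K_den(x_i - ghat(x_i | c_i))
#          * ghat(D_i = 0 | x_i) / ghat(D_i = 0 | x_i, c_i)
#
# where ghat(x | c) is a gradient-boosted regression of the exposure on
# the confounders (the generalized-propensity-score model), K_num is a
# kernel density fit on the centered exposures, K_den a kernel density
# fit on the exposure residuals, and the final ratio of boosted survival
# probabilities reweights for informative mortality. The numerator terms
# stabilize the weight near 1.

#' Specification of the weighting design
#'
#' @param target_exposure One of the six window names
#'   ([window_names()]): the exposure whose weight is being designed.
#' @param confounders Character vector of confounder columns. Must
#'   include the other five exposure windows (they are mutually adjusted)
#'   plus the individual and community covariates; `NULL` selects that
#'   default set from the person-year table at fit time.
#' @param gbm_params List overriding the boosting defaults
#'   `n_trees = 500`, `learning_rate = 0.05`, `max_depth = 3`,
#'   `subsample = 0.8`, `loss = "bernoulli"`. `loss` applies to the death
#'   models: `"bernoulli"` (logistic loss, the statistically conventional
#'   choice for a binary indicator) or `"gaussian_literal"` (squared-error
#'   regression on the 0/1 indicator with predictions clipped).
#' @param kde_params List overriding `bw = "silverman"`, `adjust = 1`.
#' @param truncation Length-two percentiles `c(lower, upper)` at which
#'   the weights are capped (default `c(1, 99)`), or `NULL` for no
#'   truncation.
#' @param seed Integer seed for the boosting subsampling.
#' @return Object of class `ipw_design_spec`.
#' @export
design_spec <- function(target_exposure,
                        confounders = NULL,
                        gbm_params = list(),
                        kde_params = list(),
                        truncation = c(1, 99),
                        seed = 1L) {
  if (!target_exposure %in% window_names()) {
    abort(paste0(
      "target_exposure must be one of: ",
      paste(window_names(), collapse = ", ")
    ))
  }
  gbm <- utils::modifyList(
    list(
      n_trees = 500L, learning_rate = 0.05, max_depth = 3L,
      subsample = 0.8, loss = "bernoulli"
    ),
    gbm_params
  )
  if (!gbm$loss %in% c("bernoulli", "gaussian_literal")) {
    abort("gbm loss must be 'bernoulli' or 'gaussian_literal'")
  }
  kdep <- utils::modifyList(list(bw = "silverman", adjust = 1), kde_params)
  if (!is.null(confounders) && target_exposure %in% confounders) {
    abort("target_exposure must not appear among the confounders")
  }
  if (!is.null(truncation)) {
    if (length(truncation) != 2 || truncation[1] < 0 ||
      truncation[2] > 100 || truncation[1] >= truncation[2]) {
      abort("truncation must be percentiles c(lower, upper) with 0 <= lower < upper <= 100")
    }
  }
  structure(
    list(
      target_exposure = target_exposure,
      confounders = confounders,
      gbm_params = gbm,
      kde_params = kdep,
      truncation = truncation,
      seed = as.integer(seed)
    ),
    class = "ipw_design_spec"
  )
}

# default confounder set: everything in the person-year table except
# identifiers, the current-year concentrations, the outcome indicators
# and the target window itself
default_confounders <- function(person_years, target_exposure) {
  setdiff(
    names(person_years),
    c(
      "person_id", "year", "zip", "pm25", "no2", "Y", "D",
      target_exposure
    )
  )
}

# numeric design matrix for boosting; characters become factors, factor
# levels become indicator columns, single-level categoricals are dropped
confounder_matrix <- function(person_years, confounders) {
  dat <- as.data.frame(person_years[confounders])
  keep <- vapply(dat, function(v) {
    !((is.character(v) || is.factor(v)) && length(unique(v)) < 2)
  }, logical(1))
  dat <- dat[keep]
  dat[] <- lapply(dat, function(v) if (is.character(v)) factor(v) else v)
  if (ncol(dat) == 0) {
    return(matrix(numeric(0), nrow = nrow(person_years), ncol = 0))
  }
  model.matrix(~ . - 1, data = dat)
}

xgb_regression <- function(X, y, gbm, seed) {
  dm <- xgboost::xgb.DMatrix(X, label = y)
  params <- xgboost::xgb.params(
    objective = "reg:squarederror",
    learning_rate = gbm$learning_rate,
    max_depth = gbm$max_depth,
    subsample = gbm$subsample,
    tree_method = "hist",
    nthread = 1,
    seed = seed
  )
  model <- xgboost::xgb.train(params, dm, nrounds = gbm$n_trees, verbose = 0)
  list(model = model, pred = predict(model, dm))
}

xgb_binary <- function(X, y01, gbm, seed) {
  dm <- xgboost::xgb.DMatrix(X, label = y01)
  if (gbm$loss == "gaussian_literal") {
    params <- xgboost::xgb.params(
      objective = "reg:squarederror",
      learning_rate = gbm$learning_rate,
      max_depth = gbm$max_depth,
      subsample = gbm$subsample,
      tree_method = "hist", nthread = 1, seed = seed
    )
  } else {
    params <- xgboost::xgb.params(
      objective = "binary:logistic",
      learning_rate = gbm$learning_rate,
      max_depth = gbm$max_depth,
      subsample = gbm$subsample,
      tree_method = "hist", nthread = 1, seed = seed
    )
  }
  model <- xgboost::xgb.train(params, dm, nrounds = gbm$n_trees, verbose = 0)
  list(model = model, pred = predict(model, dm))
}

#' Fit the generalized-propensity-score exposure model
#'
#' Gradient-boosted regression (squared-error loss) of the target
#' exposure on the confounders. The residuals feed the denominator
#' kernel density of the stabilized weight. With `n_trees = 0` the model
#' degenerates to the sample mean (null model).
#'
#' @param person_years Person-year table.
#' @param spec An [design_spec()].
#' @return Object of class `ipw_exposure_model` with `fitted`,
#'   `residuals`, `r_squared`, `confounders`.
#' @export
fit_exposure_model <- function(person_years, spec) {
  x <- person_years[[spec$target_exposure]]
  if (length(unique(x)) < 2) {
    abort("target exposure is constant; weights are undefined")
  }
  confounders <- spec$confounders %||%
    default_confounders(person_years, spec$target_exposure)
  if (anyNA(person_years[confounders])) abort("missing confounder values")
  if (spec$gbm_params$n_trees == 0 || length(confounders) == 0) {
    fitted <- rep(mean(x), length(x))
  } else {
    X <- confounder_matrix(person_years, confounders)
    fitted <- if (ncol(X) == 0) {
      rep(mean(x), length(x))
    } else {
      xgb_regression(X, x, spec$gbm_params, spec$seed)$pred
    }
  }
  res <- x - fitted
  structure(
    list(
      fitted = fitted, residuals = res,
      r_squared = 1 - var(res) / var(x),
      confounders = confounders, target_exposure = spec$target_exposure
    ),
    class = "ipw_exposure_model"
  )
}

#' Fit the competing-risk-of-death models
#'
#' Two boosted models of survival through the person-year
#' (`D = 0`): the numerator conditions on the target exposure alone, the
#' denominator on exposure plus confounders. Their ratio reweights
#' person-years so that differential mortality associated with the
#' confounders does not distort the exposure-outcome association.
#' Predicted survival probabilities are clipped to `[1e-3, 1 - 1e-3]`.
#' If no deaths are present both probabilities are identically 1 (with a
#' warning); if everything is a death the models are undefined.
#'
#' @inheritParams fit_exposure_model
#' @return List with `surv_num` and `surv_den` (per person-year survival
#'   probabilities) and `loss`.
#' @export
fit_death_models <- function(person_years, spec) {
  d <- person_years$D
  n <- length(d)
  if (all(d == 0)) {
    warn("no deaths in the person-year table; the competing-risk factor is 1")
    return(list(surv_num = rep(1, n), surv_den = rep(1, n), loss = spec$gbm_params$loss))
  }
  if (all(d == 1)) abort("every person-year is a death; survival models undefined")
  confounders <- spec$confounders %||%
    default_confounders(person_years, spec$target_exposure)
  x <- matrix(person_years[[spec$target_exposure]],
    ncol = 1,
    dimnames = list(NULL, spec$target_exposure)
  )
  Xc <- confounder_matrix(person_years, confounders)
  clip <- function(p) pmin(pmax(p, 1e-3), 1 - 1e-3)
  surv_num <- clip(xgb_binary(x, 1 - d, spec$gbm_params, spec$seed)$pred)
  surv_den <- clip(xgb_binary(cbind(x, Xc), 1 - d, spec$gbm_params, spec$seed)$pred)
  list(surv_num = surv_num, surv_den = surv_den, loss = spec$gbm_params$loss)
}

#' Estimate stabilized inverse-probability weights
#'
#' Combines the generalized-propensity-score factor (kernel density of
#' the centered exposure over kernel density of the exposure residual)
#' with the competing-risk survival-probability ratio, then optionally
#' caps the weights at configured percentiles. The four components are
#' stored per person-year and multiply exactly to the pre-truncation
#' weight.
#'
#' @inheritParams fit_exposure_model
#' @return Object of class `ipw_weight_set`: a list with `weights`
#'   (tibble: `person_id`, `year`, `sw`, `sw_raw`, `k_num`, `k_den`,
#'   `surv_num`, `surv_den`), `diagnostics` (mean/max weight, effective
#'   sample size, exposure-model R^2, balance table) and the echoed
#'   `spec`.
#' @export
stabilized_weights <- function(person_years, spec) {
  spec$confounders <- spec$confounders %||%
    default_confounders(person_years, spec$target_exposure)
  x <- person_years[[spec$target_exposure]]
  expo <- fit_exposure_model(person_years, spec)
  death <- fit_death_models(person_years, spec)

  centered <- x - mean(x)
  kde_num <- kde(centered,
    bw = spec$kde_params$bw, adjust = spec$kde_params$adjust
  )
  kde_den <- kde(expo$residuals,
    bw = spec$kde_params$bw, adjust = spec$kde_params$adjust
  )
  k_num <- kde_num$density(centered)
  k_den <- kde_den$density(expo$residuals)

  sw_raw <- k_num / k_den * death$surv_num / death$surv_den
  if (any(!is.finite(sw_raw) | sw_raw <= 0)) {
    bad <- which(!is.finite(sw_raw) | sw_raw <= 0)
    abort(paste0(
      "nonfinite or nonpositive weights for person-year(s): ",
      paste(utils::head(
        paste0(person_years$person_id[bad], ":", person_years$year[bad]), 5
      ), collapse = ", ")
    ))
  }
  sw <- sw_raw
  if (!is.null(spec$truncation)) {
    caps <- quantile(sw_raw, spec$truncation / 100, names = FALSE)
    sw <- pmin(pmax(sw_raw, caps[1]), caps[2])
  }

  weights <- tibble::tibble(
    person_id = person_years$person_id,
    year = person_years$year,
    sw = sw, sw_raw = sw_raw,
    k_num = k_num, k_den = k_den,
    surv_num = death$surv_num, surv_den = death$surv_den
  )
  out <- structure(
    list(
      weights = weights,
      diagnostics = list(
        n = nrow(weights),
        mean_weight = mean(sw),
        mean_weight_raw = mean(sw_raw),
        max_weight = max(sw),
        ess = sum(sw)^2 / sum(sw^2),
        ess_fraction = sum(sw)^2 / sum(sw^2) / length(sw),
        ess_fraction_raw = sum(sw_raw)^2 / sum(sw_raw^2) / length(sw_raw),
        r_squared_exposure = expo$r_squared,
        kde_bandwidths = c(numerator = kde_num$h, denominator = kde_den$h)
      ),
      spec = spec
    ),
    class = "ipw_weight_set"
  )
  out$diagnostics$balance <- balance_diagnostics(person_years, out)
  out
}

#' @export
print.ipw_weight_set <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "Stabilized IPW for %s: n = %d, mean = %.3f, max = %.3f, ESS = %.0f (%.1f%%)\n",
    x$spec$target_exposure, d$n, d$mean_weight, d$max_weight,
    d$ess, 100 * d$ess_fraction
  ))
  flagged <- x$diagnostics$balance$covariate[x$diagnostics$balance$flagged]
  if (length(flagged) > 0) {
    cat(
      "covariates with weighted |association| above threshold:",
      paste(flagged, collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' Covariate balance before and after weighting
#'
#' For each confounder, the unweighted and weighted association with the
#' target exposure: Pearson correlation for continuous covariates and
#' point-biserial correlation of each level indicator for categorical
#' covariates. Covariates whose weighted absolute association exceeds
#' the threshold are flagged; zero-variance covariates report 0 with a
#' degeneracy flag.
#'
#' @param person_years Person-year table.
#' @param weights An `ipw_weight_set` (or a bare numeric weight vector).
#' @param target_exposure,confounders Required when `weights` is a bare
#'   numeric vector; otherwise read from the weight set's spec.
#' @param threshold Flagging threshold on the weighted |association|.
#' @return Tibble of class `ipw_balance`.
#' @export
balance_diagnostics <- function(person_years, weights,
                                target_exposure = NULL, confounders = NULL,
                                threshold = 0.1) {
  if (inherits(weights, "ipw_weight_set")) {
    target_exposure <- weights$spec$target_exposure
    confounders <- weights$spec$confounders
    w <- weights$weights$sw
  } else {
    w <- as.numeric(weights)
    confounders <- confounders %||%
      default_confounders(person_years, target_exposure)
  }
  if (any(!is.finite(w))) abort("weights must be finite")
  x <- person_years[[target_exposure]]

  rows <- purrr::map(confounders, function(nm) {
    v <- person_years[[nm]]
    if (is.numeric(v)) {
      cols <- stats::setNames(list(v), nm)
      type <- "continuous"
    } else {
      lv <- sort(unique(as.character(v)))
      cols <- stats::setNames(
        lapply(lv, function(l) as.numeric(v == l)),
        paste0(nm, "=", lv)
      )
      type <- "categorical"
    }
    purrr::imap(cols, function(z, label) {
      un <- weighted_cor(x, z, rep(1, length(z)))
      we <- weighted_cor(x, z, w)
      tibble::tibble(
        covariate = label, type = type,
        unweighted = as.numeric(un), weighted = as.numeric(we),
        degenerate = isTRUE(attr(we, "degenerate")),
        flagged = !isTRUE(attr(we, "degenerate")) & abs(we) > threshold
      )
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  class(rows) <- c("ipw_balance", class(rows))
  attr(rows, "target_exposure") <- target_exposure
  attr(rows, "threshold") <- threshold
  rows
}
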