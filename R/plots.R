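# ggplot2 views of the main result types.

#' Plot a stabilized weight distribution
#'
#' Histogram of the stabilized weights with the mean marked; a
#' well-stabilized design concentrates near 1.
#'
#' @param object An `ipw_weight_set`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ipw_weight_set <- function(object, bins = 60, ...) {
  dat <- object$weights
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sw)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(
      xintercept = object$diagnostics$mean_weight,
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "stabilized weight",
      y = "person-years",
      title = paste0(
        "Stabilized IPW for ", object$spec$target_exposure,
        " (ESS ", sprintf("%.0f%%", 100 * object$diagnostics$ess_fraction), ")"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot covariate balance before and after weighting
#'
#' Love plot: absolute exposure-covariate association, unweighted vs
#' weighted, with the flagging threshold marked.
#'
#' @param object An `ipw_balance` table from [balance_diagnostics()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ipw_balance <- function(object, ...) {
  long <- object %>%
    tidyr::pivot_longer(
      c("unweighted", "weighted"),
      names_to = "stage", values_to = "association"
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = abs(.data$association), y = .data$covariate,
    colour = .data$stage, shape = .data$stage
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(
      xintercept = attr(object, "threshold") %||% 0.1,
      linetype = "dotted"
    ) +
    ggplot2::labs(
      x = paste0("|association| with ", attr(object, "target_exposure")),
      y = NULL, colour = NULL, shape = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of additive-risk fits
#'
#' Risk differences (per unit exposure) with 95% intervals by exposure
#' window, faceted by analysis type.
#'
#' @param fits Fits tibble from [run_analysis_set()] or
#'   [run_pipeline()].
#' @param scale `"beta"` (risk difference) or `"cases"` (annual
#'   attributable cases).
#' @return A ggplot.
#' @export
plot_fits <- function(fits, scale = c("beta", "cases")) {
  scale <- match.arg(scale)
  dat <- fits %>% dplyr::filter(!is.na(.data$beta1))
  if (scale == "beta") {
    dat <- dat %>% dplyr::mutate(
      est = .data$beta1, lo = .data$ci_low, hi = .data$ci_high
    )
    xlab <- "risk difference per unit exposure"
  } else {
    dat <- dat %>% dplyr::mutate(
      est = .data$annual_cases, lo = .data$cases_ci_low,
      hi = .data$cases_ci_high
    )
    xlab <- "annual attributable cases per unit exposure"
  }
  dat <- dat %>% dplyr::mutate(
    label = dplyr::if_else(
      is.na(.data$subgroup), .data$target_exposure,
      paste0(.data$target_exposure, " | ", .data$subgroup)
    )
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$est, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::facet_wrap(~analysis, scales = "free_x") +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
}
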