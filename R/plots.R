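#' Goodness-of-fit plots for a population fit
#'
#' Four standard panels: observed vs typical predictions, observed vs
#' individual predictions, |IWRES| vs individual predictions and CWRES vs
#' time.
#'
#' @param object A `flu_fit`.
#' @param ... Unused.
#' @return A ggplot object (facetted).
#' @export
autoplot.flu_fit <- function(object, ...) {
  g <- gof_table(object)
  long <- dplyr::bind_rows(
    tibble::tibble(panel = "DV vs PRED", x = g$pred, y = g$dv),
    tibble::tibble(panel = "DV vs IPRED", x = g$ipred, y = g$dv),
    tibble::tibble(panel = "|IWRES| vs IPRED", x = g$ipred, y = abs(g$iwres)),
    tibble::tibble(panel = "CWRES vs time", x = g$time, y = g$cwres)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Goodness of fit") +
    ggplot2::theme_minimal()
}

#' Plot a prediction-corrected visual predictive check
#'
#' Observed prediction-corrected percentiles (lines) over the simulated 95\%
#' prediction intervals of the same percentiles (ribbons).
#'
#' @param object A `flu_vpc` from [pcvpc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flu_vpc <- function(object, ...) {
  b <- object$bins
  ggplot2::ggplot(b, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p2.5_lo,
                                      ymax = .data$sim_p2.5_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p50_lo,
                                      ymax = .data$sim_p50_hi),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p97.5_lo,
                                      ymax = .data$sim_p97.5_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50), color = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p2.5), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p97.5), linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "prediction-corrected conc (ng/mL)",
                  title = sprintf("pcVPC (%d replicates)", object$n_sim)) +
    ggplot2::theme_minimal()
}

#' Plot covariate-impact typical profiles
#'
#' @param profiles Tibble from [covariate_impact_profiles()].
#' @return A ggplot object.
#' @export
plot_covariate_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$time, y = .data$conc,
                               color = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "concentration (ng/mL)") +
    ggplot2::theme_minimal()
}
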