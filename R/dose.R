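#' Exposure-targeted dose individualization
#'
#' Recommends the remaining fludarabine doses needed to reach a cumulative
#' AUC target, using the subject's MAP (empirical-Bayes) clearance from the
#' observations collected so far. Linear kinetics make total exposure
#' additive, AUC(0, Inf) = dose / CL per dose, so the outstanding exposure
#' `target - accrued` is split evenly over the remaining doses via
#' `dose = CL x AUC_share`. No default target is shipped: the choice of AUC
#' target is a clinical decision.
#'
#' @param subject_data Dataset rows for one subject (doses given so far and
#'   any observations).
#' @param fit A `flu_fit` (or a list with `theta`, `omega`, `sigma`,
#'   `model`).
#' @param target_cum_auc Cumulative AUC target in mg h/L (f-ara-A).
#' @param remaining_doses Number of doses still to give.
#' @return A tibble with one row per remaining dose (`dose_number`,
#'   `amount` in mg f-ara-A) and attributes `cl` (MAP clearance),
#'   `accrued_auc`, `predicted_cum_auc` and `based_on` (`"map"` or
#'   `"typical"` when the subject has no usable observations).
#' @export
dose_recommend <- function(subject_data, fit, target_cum_auc,
                           remaining_doses) {
  if (missing(target_cum_auc) || !is.numeric(target_cum_auc) ||
      target_cum_auc <= 0) {
    abort("target_cum_auc (mg h/L) is required and must be positive")
  }
  if (remaining_doses < 1) abort("remaining_doses must be at least 1")
  ranef <- flu_ranef(omega = fit$omega, sigma = fit$sigma)
  mp <- map_estimate(subject_data, theta = fit$theta, ranef = ranef,
                     model = fit$model)
  based_on <- if (mp$n_obs[1] > 0) "map" else "typical"
  if (based_on == "typical") {
    warn("no usable observations: recommendation based on typical values")
  }
  cl <- mp$cl[1]
  d <- as.data.frame(subject_data)
  given <- d[d$EVID == 1 & !is.na(d$AMT), , drop = FALSE]
  accrued <- sum(given$AMT) / cl # AUC(0, Inf) of doses already given
  outstanding <- target_cum_auc - accrued
  if (outstanding <= 0) {
    warn(sprintf("target %.3g mg h/L already exceeded by accrued %.3g; recommending zero doses",
                 target_cum_auc, accrued))
    amounts <- rep(0, remaining_doses)
  } else {
    amounts <- rep(cl * outstanding / remaining_doses, remaining_doses)
  }
  out <- tibble::tibble(dose_number = nrow(given) + seq_len(remaining_doses),
                        amount = amounts)
  attr(out, "cl") <- cl
  attr(out, "accrued_auc") <- accrued
  attr(out, "predicted_cum_auc") <- accrued + sum(amounts) / cl
  attr(out, "based_on") <- based_on
  out
}
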