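#' Fixed-effect parameters of the final covariate model
#'
#' Container for the fixed effects (thetas) of the fludarabine population
#' model. Clearance is split into a non-renal component specific to the CAR-T
#' construct and a renal component proportional to creatinine clearance
#' normalized by the reference value; volumes scale linearly with body weight
#' and clearances allometrically with exponent 3/4. Defaults are the final
#' published population estimates.
#'
#' @param theta_cart1 Non-renal clearance for axi-cel patients (L/h).
#' @param theta_cart2 Non-renal clearance for tisa-cel patients (L/h).
#' @param theta_crcl Renal clearance at the reference creatinine clearance
#'   (L/h).
#' @param theta_v1,theta_v2,theta_v3 Central, shallow-peripheral and
#'   deep-peripheral volumes at the reference weight (L).
#' @param theta_cld2,theta_cld3 Inter-compartmental clearances at the
#'   reference weight (L/h).
#' @param crcl_ref Reference creatinine clearance (mL/min).
#' @param wgt_ref Reference body weight (kg).
#'
#' @return An object of class `flu_theta` (a named list).
#' @examples
#' th <- flu_theta()
#' th$theta_v1 # 41.2 L
#' @export
flu_theta <- function(theta_cart1 = 4.4, theta_cart2 = 3.9, theta_crcl = 1.7,
                      theta_v1 = 41.2, theta_v2 = 14.5, theta_v3 = 10.8,
                      theta_cld2 = 4.8, theta_cld3 = 3.6,
                      crcl_ref = 96, wgt_ref = 70) {
  th <- list(theta_cart1 = theta_cart1, theta_cart2 = theta_cart2,
             theta_crcl = theta_crcl, theta_v1 = theta_v1,
             theta_v2 = theta_v2, theta_v3 = theta_v3,
             theta_cld2 = theta_cld2, theta_cld3 = theta_cld3,
             crcl_ref = crcl_ref, wgt_ref = wgt_ref)
  bad <- names(th)[!vapply(th, function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    abort(paste0("flu_theta fields must be single positive numbers; offending: ",
                 paste(bad, collapse = ", ")))
  }
  structure(th, class = "flu_theta")
}

#' @export
print.flu_theta <- function(x, ...) {
  cat("<flu_theta> fixed effects\n")
  cat(sprintf("  CL non-renal: axi-cel %.3g, tisa-cel %.3g L/h; renal %.3g L/h at CRCL %g mL/min\n",
              x$theta_cart1, x$theta_cart2, x$theta_crcl, x$crcl_ref))
  cat(sprintf("  V1/V2/V3: %.3g/%.3g/%.3g L; CLD2/CLD3: %.3g/%.3g L/h (at %g kg)\n",
              x$theta_v1, x$theta_v2, x$theta_v3, x$theta_cld2, x$theta_cld3,
              x$wgt_ref))
  invisible(x)
}

#' Between-subject variability and residual error specification
#'
#' Log-normal interindividual variability on clearance and central volume with
#' a full 2x2 covariance block, plus the residual SD of the additive error on
#' the natural-log concentration scale. Defaults reproduce the published
#' estimates: CV 29.8\% on CL, 34.8\% on V1, random-effect correlation 0.9 and
#' residual SD 0.29 log(ng/mL).
#'
#' @param cv_cl,cv_v1 Interindividual variability on CL and V1 as CV\%
#'   (converted internally to log-scale variances).
#' @param corr Correlation between the CL and V1 random effects.
#' @param sigma Residual SD on the natural-log concentration scale.
#' @param omega Optional explicit 2x2 covariance matrix on log scale;
#'   overrides `cv_cl`, `cv_v1` and `corr` when given.
#'
#' @return An object of class `flu_ranef` with elements `omega` (2x2 matrix)
#'   and `sigma`.
#' @examples
#' flu_ranef()          # published values
#' flu_ranef(omega = diag(2) * 0, sigma = 1e-6) # (near) no variability
#' @export
flu_ranef <- function(cv_cl = 29.8, cv_v1 = 34.8, corr = 0.9, sigma = 0.29,
                      omega = NULL) {
  if (is.null(omega)) {
    w_cl <- cv_percent(cv_cl, inverse = TRUE)
    w_v1 <- cv_percent(cv_v1, inverse = TRUE)
    omega <- matrix(c(w_cl, corr * sqrt(w_cl * w_v1),
                      corr * sqrt(w_cl * w_v1), w_v1), 2, 2)
  }
  omega <- as.matrix(omega)
  if (!all(dim(omega) == c(2, 2)) || max(abs(omega - t(omega))) > 1e-12) {
    abort("omega must be a symmetric 2x2 matrix")
  }
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    abort("omega must be positive semi-definite")
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("sigma must be a single positive number")
  }
  structure(list(omega = omega, sigma = sigma), class = "flu_ranef")
}

#' @export
print.flu_ranef <- function(x, ...) {
  cat("<flu_ranef>\n  omega (log-scale covariance of eta_CL, eta_V1):\n")
  print(round(x$omega, 5))
  cat(sprintf("  IIV CV%%: CL %.1f, V1 %.1f; correlation %.3f\n",
              cv_percent(x$omega[1, 1]), cv_percent(x$omega[2, 2]),
              ranef_corr(x)))
  cat(sprintf("  residual SD (log scale): %.4g\n", x$sigma))
  invisible(x)
}

ranef_corr <- function(spec) {
  o <- spec$omega
  d <- sqrt(o[1, 1] * o[2, 2])
  if (d == 0) return(NA_real_)
  o[1, 2] / d
}

#' Convert between a log-scale variance and a coefficient of variation
#'
#' For log-normally distributed individual parameters the variability is
#' reported as CV\% = sqrt(exp(omega^2) - 1) * 100, where omega^2 is the
#' variance of the random effect on log scale. The inverse maps a CV\% back
#' to the log-scale variance, ln(1 + (CV/100)^2).
#'
#' @param x Log-scale variance (forward) or CV\% (when `inverse = TRUE`).
#' @param inverse If `TRUE`, convert CV\% to variance.
#' @return CV\% or a variance.
#' @examples
#' cv_percent(0.0850)                 # ~29.8
#' cv_percent(29.8, inverse = TRUE)   # ~0.0850
#' @export
cv_percent <- function(x, inverse = FALSE) {
  if (!is.numeric(x) || any(x < 0)) {
    abort("cv_percent needs a non-negative numeric input")
  }
  if (inverse) log(1 + (x / 100)^2) else sqrt(exp(x) - 1) * 100
}
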