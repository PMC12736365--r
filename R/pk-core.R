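#' Allometric body-size scaling factor
#'
#' Power scaling of a parameter with body weight relative to a reference
#' weight: `(wgt / ref)^exponent`. The model fixes the exponent at 3/4 for
#' clearances and 1 for volumes.
#'
#' @param wgt Body weight (kg); vectorized.
#' @param ref Reference weight (kg), default 70.
#' @param exponent Allometric exponent.
#' @return Dimensionless scale factor(s).
#' @examples
#' allometric_size(140, 70, 0.75) # 2^0.75
#' @export
allometric_size <- function(wgt, ref = 70, exponent = 0.75) {
  if (!is.numeric(wgt) || any(!is.finite(wgt)) || any(wgt <= 0)) {
    abort("weight must be positive and finite")
  }
  if (ref <= 0) abort("reference weight must be positive")
  (wgt / ref)^exponent
}

# normalize CAR-T construct coding to integer 1 (axi-cel) / 2 (tisa-cel)
cart_code <- function(cart) {
  if (is.numeric(cart)) {
    out <- as.integer(cart)
  } else {
    x <- tolower(as.character(cart))
    out <- ifelse(x %in% c("axi-cel", "axicel", "axi", "1"), 1L,
                  ifelse(x %in% c("tisa-cel", "tisacel", "tisa", "2"), 2L, NA_integer_))
  }
  if (any(is.na(out) | !(out %in% c(1L, 2L)))) {
    abort("unknown CAR-T construct; expected 'axi-cel'/'tisa-cel' (or codes 1/2)")
  }
  out
}

#' Individual pharmacokinetic parameters from covariates and random effects
#'
#' Applies the final covariate model to each row of a covariate table and
#' returns the six structural parameters. Clearance combines a
#' construct-specific non-renal component with a renal component linear in
#' creatinine clearance, scaled allometrically with weight; V1-V3 scale
#' linearly with weight and the distribution clearances allometrically:
#' \deqn{CL = [\theta_{CART} + \theta_{CRCL} \cdot CRCL/96] (WGT/70)^{3/4} e^{\eta_{CL}}}
#' \deqn{V1 = \theta_{V1} (WGT/70) e^{\eta_{V1}}}
#'
#' @param covs Data frame with columns `wgt` (kg), `crcl` (mL/min) and `cart`
#'   (`"axi-cel"`/`"tisa-cel"` or codes 1/2); one row per subject.
#' @param theta A [flu_theta()] object.
#' @param eta_cl,eta_v1 Log-scale random-effect deviations (scalar or one per
#'   row).
#' @return A tibble with columns `cl`, `v1`, `v2`, `v3`, `cld2`, `cld3`
#'   (L and L/h), one row per input row.
#' @examples
#' individual_params(data.frame(wgt = 70, crcl = 96, cart = "axi-cel"))
#' @export
individual_params <- function(covs, theta = flu_theta(), eta_cl = 0, eta_v1 = 0) {
  covs <- as.data.frame(covs)
  need <- c("wgt", "crcl", "cart")
  miss <- setdiff(need, names(covs))
  if (length(miss)) abort(paste("missing covariate column(s):", paste(miss, collapse = ", ")))
  if (any(covs$wgt <= 0) || any(covs$crcl <= 0)) {
    abort("wgt and crcl must be strictly positive")
  }
  code <- cart_code(covs$cart)
  f <- allometric_size(covs$wgt, theta$wgt_ref, 0.75)
  g <- allometric_size(covs$wgt, theta$wgt_ref, 1)
  cl_nr <- ifelse(code == 1L, theta$theta_cart1, theta$theta_cart2)
  cl <- (cl_nr + theta$theta_crcl * covs$crcl / theta$crcl_ref) * f * exp(eta_cl)
  tibble::tibble(
    cl = cl,
    v1 = theta$theta_v1 * g * exp(eta_v1),
    v2 = theta$theta_v2 * g,
    v3 = theta$theta_v3 * g,
    cld2 = theta$theta_cld2 * f,
    cld3 = theta$theta_cld3 * f
  )
}

params_vec <- function(params) {
  p <- as.data.frame(params)[1, c("cl", "v1", "v2", "v3", "cld2", "cld3")]
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p[1:2] <= 0) || any(p < 0)) {
    abort("pharmacokinetic parameters must be finite, cl/v1 > 0 and all >= 0")
  }
  p
}

regimen_mat <- function(regimen) {
  if (is.null(regimen) || NROW(regimen) == 0) {
    return(matrix(numeric(0), ncol = 3))
  }
  r <- as.data.frame(regimen)
  need <- c("start_time", "amount", "duration")
  miss <- setdiff(need, names(r))
  if (length(miss)) abort(paste("regimen lacks column(s):", paste(miss, collapse = ", ")))
  if (any(r$amount < 0)) abort("dose amounts must be non-negative")
  if (any(r$duration <= 0)) abort("infusion durations must be strictly positive")
  cbind(r$start_time, r$amount, r$duration)
}

#' Serum concentration of f-ara-A under a multi-dose infusion regimen
#'
#' Solves the linear three-compartment mammillary system with zero-order
#' infusion input into the central compartment, by eigendecomposition of the
#' rate matrix (matrix-exponential fallback for near-degenerate spectra), and
#' superposes all dose events. Setting `cld3 = 0` (and/or `cld2 = 0`) reduces
#' the system to two (one) compartments exactly.
#'
#' @param params One row of structural parameters with columns/elements `cl`,
#'   `v1`, `v2`, `v3`, `cld2`, `cld3` (L, L/h), e.g. from
#'   [individual_params()].
#' @param regimen Data frame of dose events with columns `start_time` (h),
#'   `amount` (mg f-ara-A) and `duration` (h), e.g. from [build_regimen()].
#' @param times Numeric vector of times (h since first dose) at which to
#'   evaluate the concentration.
#' @return Numeric vector of serum concentrations in ng/mL.
#' @examples
#' p <- individual_params(data.frame(wgt = 70, crcl = 96, cart = "axi-cel"))
#' r <- data.frame(start_time = 0, amount = 44.46, duration = 0.5)
#' pk_concentration(p, r, c(0.5, 1.5, 24))
#' @export
pk_concentration <- function(params, regimen, times) {
  if (any(times < 0)) abort("times must be non-negative")
  dm <- regimen_mat(regimen)
  if (nrow(dm) == 0) return(rep(0, length(times)))
  mgL <- cpp_conc3(params_vec(params), dm, as.numeric(times))
  as.numeric(mgL) * 1000 # mg/L -> ng/mL
}

#' Area under the concentration-time curve
#'
#' Analytic integral of the central-compartment concentration (mg/L scale)
#' over `[t0, t1]`, computed from the exponential solution rather than by
#' quadrature. `t1 = Inf` gives total exposure; for a single dose,
#' AUC(0, Inf) = dose / CL.
#'
#' @inheritParams pk_concentration
#' @param t0,t1 Integration limits (h); `t1` may be `Inf`.
#' @return AUC in mg h/L.
#' @examples
#' p <- individual_params(data.frame(wgt = 70, crcl = 96, cart = "axi-cel"))
#' r <- data.frame(start_time = 0, amount = 44.46, duration = 0.5)
#' pk_auc(p, r, 0, Inf) # = 44.46 / CL
#' @export
pk_auc <- function(params, regimen, t0 = 0, t1 = Inf) {
  if (!is.finite(t0) || t0 < 0) abort("t0 must be finite and non-negative")
  if (t1 <= t0) abort("t1 must exceed t0")
  dm <- regimen_mat(regimen)
  if (nrow(dm) == 0) return(0)
  cpp_auc3(params_vec(params), dm, t0, t1)
}
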