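#' Draw interindividual random effects
#'
#' Mean-zero bivariate normal draws of (eta_CL, eta_V1) with the log-scale
#' covariance of a [flu_ranef()] specification. A zero covariance matrix
#' yields exactly-zero draws; a fixed seed gives reproducible draws.
#'
#' @param spec A [flu_ranef()] object.
#' @param n Number of subjects.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An `n x 2` matrix with columns `eta_cl`, `eta_v1`.
#' @examples
#' sample_etas(flu_ranef(), 5, seed = 1)
#' @export
sample_etas <- function(spec, n, seed = NULL) {
  if (n < 1) abort("n must be at least 1")
  eg <- eigen(spec$omega, symmetric = TRUE)
  if (min(eg$values) < -1e-10 * max(abs(eg$values), 1)) {
    abort("omega must be positive semi-definite")
  }
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 2)
  draw <- function() {
    z <- matrix(rnorm(2 * n), n, 2)
    out <- z %*% t(L)
    colnames(out) <- c("eta_cl", "eta_v1")
    out
  }
  if (is.null(seed)) draw() else run_seeded(seed, draw())
}

#' Simulate observed concentrations for one subject
#'
#' Evaluates the individual model at the sampling times and adds the residual
#' error on natural-log scale: `log(DV) = log(f(t)) + eps`,
#' `eps ~ N(0, sigma^2)`. Values below the LLOQ (above the ULOQ) are retained
#' but flagged `blq` (`aulq`); times with zero model prediction are returned
#' as censored missing values rather than log-transformed.
#'
#' @param subject A one-row data frame (or list) with covariates `wgt`,
#'   `crcl`, `cart` and a `regimen` dose-event table (list-column or separate
#'   argument).
#' @param times Sampling times (h since first dose).
#' @param theta A [flu_theta()].
#' @param ranef A [flu_ranef()].
#' @param eta Optional length-2 random-effect vector; drawn from `ranef` when
#'   `NULL`.
#' @param seed Integer seed for the subject's draws (`NULL`: current RNG).
#' @param lloq,uloq Quantification limits (ng/mL).
#' @return A tibble with `time`, `conc` (ng/mL, `NA` when unquantifiable),
#'   `blq`, `aulq` flags, and the `eta_cl`/`eta_v1` used.
#' @export
simulate_subject <- function(subject, times, theta = flu_theta(),
                             ranef = flu_ranef(), eta = NULL, seed = NULL,
                             lloq = 1, uloq = 1000) {
  if (is.data.frame(subject)) {
    subject <- lapply(subject[1, , drop = FALSE],
                      function(col) if (is.list(col)) col[[1]] else col)
  }
  regimen <- subject$regimen
  if (is.list(regimen) && !is.data.frame(regimen)) regimen <- regimen[[1]]
  covs <- data.frame(wgt = subject$wgt, crcl = subject$crcl,
                     cart = subject$cart)
  run <- function() {
    e <- if (is.null(eta)) drop(sample_etas(ranef, 1)) else as.numeric(eta)
    p <- individual_params(covs, theta, eta_cl = e[1], eta_v1 = e[2])
    if (is.null(regimen) || NROW(regimen) == 0) {
      if (length(times)) warn("empty regimen with sampling times: all observations censored")
      cmod <- rep(0, length(times))
    } else {
      cmod <- pk_concentration(p, regimen, times)
    }
    eps <- rnorm(length(times), 0, ranef$sigma)
    conc <- ifelse(cmod > 0, exp(log(cmod) + eps), NA_real_)
    tibble::tibble(
      time = as.numeric(times),
      conc = conc,
      blq = is.na(conc) | conc < lloq,
      aulq = !is.na(conc) & conc > uloq,
      eta_cl = e[1], eta_v1 = e[2]
    )
  }
  if (is.null(seed)) run() else run_seeded(seed, run())
}
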