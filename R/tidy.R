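#' Tidy a population fit into a parameter table
#'
#' One row per reported quantity, formatted the way population-PK parameter
#' tables are presented: fixed effects with (when computed) RSE\%, the
#' interindividual variabilities as CV\% with their shrinkage, the
#' random-effect correlation, and the residual SD with epsilon-shrinkage.
#'
#' @param x A `flu_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `rse`, `shrinkage`.
#' @export
tidy.flu_fit <- function(x, ...) {
  nm <- model_param_names(x$model)
  fixed <- tibble::tibble(
    term = nm,
    estimate = vapply(nm, function(n) x$theta[[n]], numeric(1)),
    rse = NA_real_, shrinkage = NA_real_
  )
  rand <- tibble::tibble(
    term = c("iiv_cl_cv", "iiv_v1_cv", "corr_cl_v1", "sigma_log"),
    estimate = c(cv_percent(x$omega[1, 1]), cv_percent(x$omega[2, 2]),
                 x$corr, x$sigma),
    rse = NA_real_,
    shrinkage = c(x$eta_shrinkage, NA_real_, x$eps_shrinkage)
  )
  out <- dplyr::bind_rows(fixed, rand)
  if (!is.null(x$se)) {
    se_map <- setNames(x$se$rse, x$se$term)
    out$rse <- dplyr::case_when(
      out$term %in% names(se_map) ~ unname(se_map[out$term]),
      out$term == "sigma_log" ~ unname(se_map["sigma"]),
      out$term == "corr_cl_v1" ~ unname(se_map["corr"]),
      out$term == "iiv_cl_cv" ~ unname(se_map["omega_cl"]),
      out$term == "iiv_v1_cv" ~ unname(se_map["omega_v1"]),
      TRUE ~ NA_real_
    )
  }
  out
}

#' One-row summary of a population fit
#'
#' @param x A `flu_fit`.
#' @param ... Unused.
#' @return A tibble with the OFV, data size, convergence code and
#'   variability summaries.
#' @export
glance.flu_fit <- function(x, ...) {
  tibble::tibble(
    ofv = x$ofv, n_subjects = x$n_subjects, n_obs = x$n_obs,
    convergence = x$convergence$code,
    iiv_cl_cv = cv_percent(x$omega[1, 1]),
    iiv_v1_cv = cv_percent(x$omega[2, 2]),
    corr_cl_v1 = x$corr, sigma = x$sigma
  )
}
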