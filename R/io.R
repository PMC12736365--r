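#' Read / write the longitudinal dataset
#'
#' CSV dialect with NONMEM-compatible column semantics: `ID`, `TIME` (h since
#' first dose), `AMT` (mg f-ara-A; empty on observation rows), `DUR` (h),
#' `DV` (ng/mL), `EVID` (1 dose / 0 observation), `MDV`, `BLQ`, `ALQ`, and
#' covariates `WT`, `CRCL`, `CART` (1 axi-cel / 2 tisa-cel), `AGE`, `SEX`,
#' `HT`, `SCR`. Unknown columns are preserved. `amp_doses = TRUE` declares
#' that `AMT` carries administered f-ara-AMP, converted (x 0.78) at read
#' time.
#'
#' @param path File path.
#' @param amp_doses If `TRUE`, convert `AMT` from f-ara-AMP to f-ara-A on
#'   read.
#' @return A validated tibble.
#' @export
read_pk_dataset <- function(path, amp_doses = FALSE) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (amp_doses) {
    message("converting AMT from f-ara-AMP to f-ara-A (x 0.78)")
    dose_rows <- !is.na(d$AMT)
    d$AMT[dose_rows] <- fara_a_equivalent(d$AMT[dose_rows])
  }
  validate_pk_dataset(d)
}

#' @rdname read_pk_dataset
#' @param data Dataset tibble.
#' @export
write_pk_dataset <- function(data, path) {
  validate_pk_dataset(data)
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Validate a dataset tibble
#'
#' Checks the mandatory columns, dose-row and observation-row contracts, and
#' that `TIME` is non-decreasing within each subject.
#'
#' @param data Dataset tibble.
#' @return The data, invisibly usable, as a tibble.
#' @export
validate_pk_dataset <- function(data) {
  d <- tibble::as_tibble(data)
  mandatory <- c("ID", "TIME", "AMT", "DUR", "DV", "EVID", "WT", "CRCL", "CART")
  miss <- setdiff(mandatory, names(d))
  if (length(miss)) {
    abort(paste("dataset is missing mandatory column(s):",
                paste(miss, collapse = ", ")))
  }
  for (cc in c("MDV", "BLQ", "ALQ")) if (is.null(d[[cc]])) d[[cc]] <- 0L
  if (nrow(d) == 0) return(d)
  bad_dose <- d$EVID == 1 & (is.na(d$AMT) | d$AMT <= 0)
  if (any(bad_dose)) {
    abort(paste("dose rows (EVID=1) must have AMT > 0; offending rows:",
                paste(which(bad_dose), collapse = ", ")))
  }
  bad_obs <- d$EVID == 0 & is.na(d$DV) & d$MDV == 0 & d$BLQ == 0 & d$ALQ == 0
  if (any(bad_obs)) {
    abort(paste("observation rows need DV or a censor/missing flag; rows:",
                paste(which(bad_obs), collapse = ", ")))
  }
  non_mono <- vapply(split(d$TIME, d$ID), is.unsorted, logical(1))
  if (any(non_mono)) {
    abort(paste("TIME must be non-decreasing within subject; offending id(s):",
                paste(names(non_mono)[non_mono], collapse = ", ")))
  }
  if (!all(d$CART %in% c(1, 2))) abort("CART must be coded 1 (axi-cel) or 2 (tisa-cel)")
  d
}

#' Read / write a run configuration
#'
#' YAML round-trip of estimation, simulation and VPC settings.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config Named list of settings.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
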