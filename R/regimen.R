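#' Convert an administered f-ara-AMP dose to f-ara-A equivalents
#'
#' Fludarabine is administered as the monophosphate prodrug (f-ara-AMP) while
#' the measured circulating analyte is f-ara-A; dose equivalents follow from
#' the molecular-weight ratio 0.78.
#'
#' @param dose_amp Administered dose (mg f-ara-AMP); vectorized.
#' @return Dose in mg f-ara-A.
#' @examples
#' fara_a_equivalent(100) # 78
#' @export
fara_a_equivalent <- function(dose_amp) {
  if (any(dose_amp < 0)) abort("dose must be non-negative")
  0.78 * dose_amp
}

#' Renal dose-adjustment fraction
#'
#' Protocolized fludarabine dose reduction by renal function: full dose at
#' eGFR >= 60 mL/min, a 25\% reduction for 45-60 mL/min and a 40\% reduction
#' for 30-45 mL/min. At exactly 45 or 60 the higher fraction applies. The
#' protocol is silent below 30 mL/min, which is surfaced as an error.
#'
#' @param egfr Estimated glomerular filtration rate (mL/min); vectorized.
#' @return Fraction of the full dose (1, 0.75 or 0.6).
#' @examples
#' renal_adjustment_fraction(c(96, 50, 40))
#' @export
renal_adjustment_fraction <- function(egfr) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) abort("egfr must be positive")
  if (any(egfr < 30)) {
    abort("eGFR below 30 mL/min is outside the dosing protocol; no reduction rule is defined")
  }
  ifelse(egfr >= 60, 1, ifelse(egfr >= 45, 0.75, 0.60))
}

#' Body surface area
#'
#' Du Bois formula (default), `0.007184 * height^0.725 * weight^0.425`, or
#' Mosteller, `sqrt(height * weight / 3600)`.
#'
#' @param height Height (cm); vectorized.
#' @param weight Weight (kg); vectorized.
#' @param method `"dubois"` or `"mosteller"`.
#' @return BSA in m^2.
#' @examples
#' bsa(180, 80)
#' @export
bsa <- function(height, weight, method = c("dubois", "mosteller")) {
  method <- match.arg(method)
  if (any(height <= 0) || any(weight <= 0)) abort("height and weight must be positive")
  switch(method,
    dubois = 0.007184 * height^0.725 * weight^0.425,
    mosteller = sqrt(height * weight / 3600)
  )
}

#' Cockcroft-Gault creatinine clearance
#'
#' `(140 - age) * weight / (72 * scr)`, multiplied by 0.85 for women.
#' Absolute clearance in mL/min (not BSA-normalized).
#'
#' @param age Age (years); must be below 140.
#' @param weight Weight (kg).
#' @param scr Serum creatinine (mg/dL).
#' @param sex `"male"`/`"female"` (or 1/2).
#' @return Creatinine clearance (mL/min).
#' @examples
#' cockcroft_gault(59, 80, 1.0, "male") # 90
#' @export
cockcroft_gault <- function(age, weight, scr, sex) {
  if (any(age <= 0) || any(weight <= 0) || any(scr <= 0)) {
    abort("age, weight and scr must be positive")
  }
  if (any(age >= 140)) abort("age must be below 140 years")
  fem <- sex_is_female(sex)
  (140 - age) * weight / (72 * scr) * ifelse(fem, 0.85, 1)
}

sex_is_female <- function(sex) {
  if (is.numeric(sex)) return(as.integer(sex) == 2L)
  tolower(as.character(sex)) %in% c("female", "f", "2")
}

#' Product-specific lymphodepletion regimen specification
#'
#' Three once-daily 30-minute infusions on consecutive days; 30 mg/m^2
#' f-ara-AMP per dose for axi-cel, 25 mg/m^2 for tisa-cel (cyclophosphamide
#' is co-administered but never dose-adjusted or modeled here).
#'
#' @param product `"axi-cel"` or `"tisa-cel"`.
#' @param dose_per_m2 Dose per m^2 in mg f-ara-AMP; defaults by product.
#' @param day_times Dose start offsets (h since first dose).
#' @param infusion_duration Infusion length (h).
#' @return A `flu_regimen_spec` list.
#' @export
regimen_spec <- function(product = c("axi-cel", "tisa-cel"),
                         dose_per_m2 = NULL,
                         day_times = c(0, 24, 48),
                         infusion_duration = 0.5) {
  product <- match.arg(product)
  if (is.null(dose_per_m2)) {
    dose_per_m2 <- if (product == "axi-cel") 30 else 25
  }
  if (dose_per_m2 <= 0) abort("dose_per_m2 must be positive")
  if (infusion_duration <= 0) abort("infusion_duration must be positive")
  structure(list(product = product, dose_per_m2 = dose_per_m2,
                 day_times = day_times, infusion_duration = infusion_duration),
            class = "flu_regimen_spec")
}

#' Build a dose-event table for one patient
#'
#' Expands a regimen specification into dose events: amount per event is
#' `dose_per_m2 * bsa * renal_adjustment_fraction(egfr) * 0.78` mg f-ara-A
#' (the conversion to the measured analyte happens here, once). Amounts are
#' not rounded to vial sizes.
#'
#' @param spec A [regimen_spec()] (or a product name, for convenience).
#' @param bsa Body surface area (m^2).
#' @param egfr eGFR (mL/min) used for the renal adjustment.
#' @return A tibble of dose events: `start_time` (h), `amount` (mg f-ara-A),
#'   `duration` (h).
#' @examples
#' build_regimen("axi-cel", bsa = 1.8, egfr = 96)
#' @export
build_regimen <- function(spec, bsa, egfr) {
  if (is.character(spec)) spec <- regimen_spec(spec)
  frac <- renal_adjustment_fraction(egfr)
  amt <- fara_a_equivalent(spec$dose_per_m2 * bsa) * frac
  tibble::tibble(
    start_time = as.numeric(spec$day_times),
    amount = rep(amt, length(spec$day_times)),
    duration = rep(spec$infusion_duration, length(spec$day_times))
  )
}
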