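# Expensive simulation-estimation experiments shared across test files,
# computed lazily once per test run.

.flupk_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.flupk_test_cache[[key]])) {
    assign(key, force(expr), envir = .flupk_test_cache)
  }
  get(key, envir = .flupk_test_cache)
}

# perturbed starting values for a replicate: true fixed effects jittered by
# 10% log-normal, variability initialized away from the truth
perturbed_init <- function(rep_seed) {
  th_true <- unclass(flu_theta())
  set.seed(1000 + rep_seed)
  th <- as.list(setNames(unlist(th_true[1:8]) * exp(rnorm(8, 0, 0.1)),
                         names(th_true)[1:8]))
  th$wgt_ref <- 70
  th$crcl_ref <- 96
  list(theta = th,
       ranef = flu_ranef(cv_cl = 25, cv_v1 = 40, corr = 0.7, sigma = 0.35))
}

replicate_study <- function(rep_seed) {
  cached(paste0("study", rep_seed), {
    co <- generate_cohort(cohort_spec(n = 56), seed = rep_seed)
    generate_study(co, seed = rep_seed)
  })
}

replicate_fit <- function(rep_seed) {
  cached(paste0("fit", rep_seed), {
    fit_population(replicate_study(rep_seed), init = perturbed_init(rep_seed))
  })
}

reduced_fit_seed1 <- function() {
  cached("fit1_reduced", {
    fit_population(replicate_study(1), model = flu_model(cl_renal = FALSE),
                   init = perturbed_init(1))
  })
}

# one-subject dataset builder used across estimation and acceptance tests
make_subject_data <- function(id = 1, times, theta = flu_theta(),
                              ranef = flu_ranef(), seed = 1,
                              wgt = 70, crcl = 96, cart = 1, eta = NULL) {
  reg <- build_regimen(if (cart == 1) "axi-cel" else "tisa-cel",
                       bsa = 1.9, egfr = crcl)
  sub <- tibble::tibble(wgt = wgt, crcl = crcl, cart = cart,
                        regimen = list(reg))
  obs <- simulate_subject(sub, times, theta, ranef, eta = eta, seed = seed)
  dplyr::bind_rows(
    tibble::tibble(ID = id, TIME = reg$start_time, AMT = reg$amount,
                   DUR = reg$duration, DV = NA_real_, EVID = 1L, MDV = 1L,
                   BLQ = 0L, ALQ = 0L),
    tibble::tibble(ID = id, TIME = obs$time, AMT = NA_real_, DUR = NA_real_,
                   DV = obs$conc, EVID = 0L, MDV = 0L, BLQ = 0L, ALQ = 0L)
  ) |>
    dplyr::mutate(WT = wgt, CRCL = crcl, CART = cart, AGE = 60, SEX = 1,
                  HT = 175, SCR = 1) |>
    dplyr::arrange(TIME, -EVID)
}

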