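test_that("goodness-of-fit residual identities hold in degenerate cases", {
  co <- generate_cohort(cohort_spec(n = 6), seed = 81)
  # no interindividual variability: PRED equals IPRED exactly
  ds0 <- generate_study(co, ranef = flu_ranef(omega = matrix(0, 2, 2),
                                              sigma = 0.29), seed = 81)
  f0 <- flu_fit_at(ds0, ranef = flu_ranef(omega = diag(1e-12, 2),
                                          sigma = 0.29))
  g0 <- gof_table(f0)
  expect_equal(g0$pred, g0$ipred, tolerance = 1e-4)
  # near-noiseless observations: IWRES ~ 0
  ds1 <- generate_study(co, ranef = flu_ranef(sigma = 1e-9), seed = 82)
  f1 <- flu_fit_at(ds1, ranef = flu_ranef(sigma = 1e-4))
  g1 <- gof_table(f1)
  expect_lt(max(abs(g1$iwres)), 1e-2)
  expect_equal(nrow(g1), sum(ds1$EVID == 0 & ds1$BLQ == 0 & ds1$ALQ == 0))
})

test_that("conditional weighted residuals are calibrated under the true model", {
  co <- generate_cohort(cohort_spec(n = 150), seed = 83)
  ds <- generate_study(co, design_spec(p_7h = 0, lloq = 0, uloq = Inf),
                       seed = 83)
  f <- flu_fit_at(ds)
  g <- gof_table(f)
  expect_equal(mean(g$cwres), 0, tolerance = 0.05)
  expect_equal(sd(g$cwres), 1, tolerance = 0.1)
  expect_true(all(is.finite(g$iwres)))
})

test_that("prediction correction is the identity for homogeneous bins", {
  co <- generate_cohort(cohort_spec(n = 12), seed = 84)
  co$wgt <- 75; co$crcl <- 96; co$cart <- "axi-cel"
  co$regimen <- replicate(12, build_regimen("axi-cel", 1.9, 96),
                          simplify = FALSE)
  ds <- generate_study(co, design_spec(p_7h = 0), seed = 84)
  f <- flu_fit_at(ds)
  v <- pcvpc(f, n_sim = 30, seed = 2)
  # identical covariates: pc-observed percentiles equal raw percentiles
  obs <- ds[ds$EVID == 0 & ds$BLQ == 0 & ds$ALQ == 0 & ds$MDV == 0, ]
  for (b in v$bins$bin) {
    raw <- quantile(obs$DV[obs$TIME == b], c(0.025, 0.5, 0.975))
    got <- unlist(v$bins[v$bins$bin == b,
                         c("obs_p2.5", "obs_p50", "obs_p97.5")])
    expect_equal(unname(got), unname(raw), tolerance = 1e-10)
  }
})

test_that("a single simulated replicate collapses the prediction intervals", {
  co <- generate_cohort(cohort_spec(n = 10), seed = 85)
  ds <- generate_study(co, seed = 85)
  f <- flu_fit_at(ds)
  v1 <- pcvpc(f, n_sim = 1, seed = 3)
  expect_equal(v1$bins$sim_p50_lo, v1$bins$sim_p50_hi)
  expect_equal(v1$bins$sim_p2.5_lo, v1$bins$sim_p2.5_hi)
})

test_that("pcVPC on self-simulated data shows near-nominal coverage", {
  co <- generate_cohort(cohort_spec(n = 40), seed = 86)
  ds <- generate_study(co, seed = 86)
  f <- flu_fit_at(ds) # the generating model itself
  v <- pcvpc(f, n_sim = 300, seed = 4)
  b <- v$bins
  inside <- c(b$obs_p2.5 >= b$sim_p2.5_lo & b$obs_p2.5 <= b$sim_p2.5_hi,
              b$obs_p50 >= b$sim_p50_lo & b$obs_p50 <= b$sim_p50_hi,
              b$obs_p97.5 >= b$sim_p97.5_lo & b$obs_p97.5 <= b$sim_p97.5_hi)
  expect_gte(mean(inside), 0.9)
  # percentile ordering within every bin
  expect_true(all(b$obs_p2.5 <= b$obs_p50 & b$obs_p50 <= b$obs_p97.5))
  expect_true(all(b$sim_p50_lo <= b$sim_p50_hi))
})

test_that("covariate-impact profiles reproduce the clinical orderings", {
  reg <- build_regimen("axi-cel", bsa = 1.9, egfr = 96)
  tt <- seq(0, 120, by = 1)
  # identical covariates give identical profiles
  g2 <- covariate_impact_profiles(
    data.frame(wgt = c(80, 80), crcl = c(96, 96), cart = c(1, 1)),
    reg, times = tt)
  expect_equal(g2$conc[g2$scenario == g2$scenario[1]],
               g2$conc[g2$scenario == g2$scenario[nrow(g2)]])
  # renal function: lower eGFR accumulates - trough ordering is monotone
  gr <- covariate_impact_profiles(
    data.frame(wgt = 80, crcl = c(40, 70, 96, 150), cart = 1,
               label = paste0("crcl", c(40, 70, 96, 150))),
    reg, times = tt)
  trough <- tapply(gr$conc[gr$time == 120], gr$scenario[gr$time == 120], I)
  expect_true(all(diff(trough[paste0("crcl", c(150, 96, 70, 40))]) > 0))
  # body size: heavier patients start lower under fixed dosing
  gw <- covariate_impact_profiles(
    data.frame(wgt = c(55, 80, 100), crcl = 96, cart = 1,
               label = paste0("w", c(55, 80, 100))),
    reg, times = c(0.5, 1))
  c0 <- gw$conc[gw$time == 0.5]
  expect_true(c0[1] > c0[2] && c0[2] > c0[3])
})
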