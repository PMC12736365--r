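test_that("allometric scaling reproduces its defining power law", {
  expect_equal(allometric_size(70, 70, 0.75), 1.0)
  expect_equal(allometric_size(70, 70, 1.0), 1.0)
  expect_equal(allometric_size(140, 70, 0.75), 1.681793, tolerance = 1e-6)
  expect_error(allometric_size(-5), "positive")
  expect_error(allometric_size(0), "positive")
})

test_that("covariate model gives the published typical parameters", {
  axi <- individual_params(data.frame(wgt = 70, crcl = 96, cart = "axi-cel"))
  tisa <- individual_params(data.frame(wgt = 70, crcl = 96, cart = "tisa-cel"))
  expect_equal(axi$cl, 6.1, tolerance = 1e-12)
  expect_equal(tisa$cl, 5.6, tolerance = 1e-12)
  expect_equal(axi$v1, 41.2)
  expect_equal(axi$v2, 14.5)
  expect_equal(axi$v3, 10.8)
  # reduced renal function, tisa-cel: 3.9 + 1.7 * 48/96
  half <- individual_params(data.frame(wgt = 70, crcl = 48, cart = "tisa-cel"))
  expect_equal(half$cl, 4.75, tolerance = 1e-12)
  # eta enters multiplicatively on the log scale
  up <- individual_params(data.frame(wgt = 70, crcl = 96, cart = 1),
                          eta_cl = 0.3, eta_v1 = -0.2)
  expect_equal(up$cl, 6.1 * exp(0.3))
  expect_equal(up$v1, 41.2 * exp(-0.2))
  expect_error(
    individual_params(data.frame(wgt = 70, crcl = 96, cart = "other")),
    "construct")
})

test_that("concentration is causal, continuous and zero without doses", {
  p <- individual_params(data.frame(wgt = 70, crcl = 96, cart = 1))
  expect_equal(pk_concentration(p, NULL, c(0, 1, 10)), c(0, 0, 0))
  reg <- data.frame(start_time = 5, amount = 40, duration = 0.5)
  expect_equal(pk_concentration(p, reg, c(0, 2, 4.9)), c(0, 0, 0))
  # continuity across the end of the infusion
  eps <- 1e-7
  c_end <- pk_concentration(p, reg, 5.5 + c(-eps, 0, eps))
  expect_lt(diff(range(c_end)) / c_end[2], 1e-5)
})

test_that("analytic solution matches a stiff-ODE oracle across random cases", {
  set.seed(31)
  worst <- 0
  for (i in 1:100) {
    p <- random_params()
    reg <- random_regimen()
    tt <- sort(runif(6, 0.1, 80))
    ana <- pk_concentration(p, reg, tt)
    ode <- ode_oracle(p, reg, tt)
    ok <- ode > 1e-9
    worst <- max(worst, abs(ana[ok] - ode[ok]) / ode[ok])
  }
  expect_lt(worst, 1e-6)
})

test_that("dose linearity holds to numerical precision", {
  set.seed(5)
  for (i in 1:10) {
    p <- random_params()
    reg <- random_regimen(3)
    tt <- sort(runif(5, 0.5, 90))
    c1 <- pk_concentration(p, reg, tt)
    reg2 <- reg
    reg2$amount <- reg2$amount * 3.7
    c2 <- pk_concentration(p, reg2, tt)
    expect_equal(c2, 3.7 * c1, tolerance = 1e-10)
  }
})

test_that("mass is conserved: compartments plus eliminated equal dosed", {
  set.seed(11)
  p <- random_params()
  reg <- random_regimen(2)
  tt <- c(1, 10, 40, 100)
  st <- ode_oracle(p, reg, tt, with_state = TRUE)
  dosed <- vapply(tt, function(t) {
    sum(pmin(pmax(t - reg$start_time, 0), reg$duration) / reg$duration *
          reg$amount)
  }, numeric(1))
  total <- rowSums(st$amounts) + st$eliminated
  expect_equal(total, dosed, tolerance = 1e-6)
})

test_that("degenerate distribution clearances collapse to the nested models", {
  # cld2 = cld3 = 0: one-compartment bolus-limit closed form
  p1 <- tibble::tibble(cl = 5, v1 = 40, v2 = 1, v3 = 1, cld2 = 0, cld3 = 0)
  dur <- 1e-4
  reg <- data.frame(start_time = 0, amount = 50, duration = dur)
  tt <- c(1, 5, 20)
  got <- pk_concentration(p1, reg, tt)
  expected <- 50 / 40 * exp(-5 / 40 * (tt - dur / 2)) * 1000
  expect_equal(got, expected, tolerance = 1e-3)
  # cld3 = 0: matches the ODE oracle of the two-compartment system
  p2 <- tibble::tibble(cl = 6, v1 = 40, v2 = 15, v3 = 1, cld2 = 5, cld3 = 0)
  reg2 <- data.frame(start_time = 0, amount = 44, duration = 0.5)
  tt2 <- c(0.5, 2, 12, 48)
  expect_equal(pk_concentration(p2, reg2, tt2), ode_oracle(p2, reg2, tt2),
               tolerance = 1e-6)
})

test_that("AUC is analytic, additive, and AUC(0,Inf) = dose/CL", {
  p <- individual_params(data.frame(wgt = 70, crcl = 96, cart = 1))
  reg1 <- data.frame(start_time = 0, amount = 44.46, duration = 0.5)
  expect_equal(pk_auc(p, NULL, 0, Inf), 0)
  expect_equal(pk_auc(p, reg1, 0, Inf), 7.288525, tolerance = 1e-6)
  set.seed(17)
  for (i in 1:10) {
    pr <- random_params()
    reg <- random_regimen()
    expect_equal(pk_auc(pr, reg, 0, Inf),
                 sum(reg$amount) / pr$cl, tolerance = 1e-9)
    t1 <- runif(1, 1, 40); t2 <- t1 + runif(1, 1, 60)
    expect_equal(pk_auc(pr, reg, 0, t1) + pk_auc(pr, reg, t1, t2),
                 pk_auc(pr, reg, 0, t2), tolerance = 1e-9)
  }
  # AUC over a finite window agrees with fine trapezoidal quadrature
  tt <- seq(0, 30, by = 0.002)
  cc <- pk_concentration(p, reg1, tt) / 1000
  trap <- sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt))
  expect_equal(pk_auc(p, reg1, 0, 30), trap, tolerance = 1e-5)
  expect_error(pk_auc(p, reg1, 10, 2), "exceed")
})
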