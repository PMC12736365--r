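# Independent numerical oracles used across test files.

# stiff-ODE solution of the three-compartment infusion system (deSolve);
# returns concentrations in ng/mL plus the full amount state for mass-balance
# checks
ode_oracle <- function(params, regimen, times, with_state = FALSE) {
  p <- as.numeric(as.data.frame(params)[1, c("cl", "v1", "v2", "v3",
                                             "cld2", "cld3")])
  reg <- as.data.frame(regimen)
  rhs <- function(t, y, pars) {
    rate <- sum(ifelse(t > reg$start_time &
                         t <= reg$start_time + reg$duration,
                       reg$amount / reg$duration, 0))
    k10 <- p[1] / p[2]
    k12 <- p[5] / p[2]; k21 <- if (p[3] > 0) p[5] / p[3] else 0
    k13 <- p[6] / p[2]; k31 <- if (p[4] > 0) p[6] / p[4] else 0
    d1 <- rate - (k10 + k12 + k13) * y[1] + k21 * y[2] + k31 * y[3]
    d2 <- k12 * y[1] - k21 * y[2]
    d3 <- k13 * y[1] - k31 * y[3]
    list(c(d1, d2, d3, k10 * y[1])) # 4th state: cumulative eliminated
  }
  tt <- sort(unique(c(0, times, reg$start_time, reg$start_time + reg$duration)))
  # cap the internal step so the integrator cannot stride across a short
  # infusion pulse without sampling it
  sol <- deSolve::lsoda(c(0, 0, 0, 0), tt, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12,
                        hmax = min(reg$duration) / 4)
  idx <- match(times, tt)
  conc <- sol[idx, 2] / p[2] * 1000
  if (!with_state) return(conc)
  list(conc = conc, amounts = sol[idx, 2:4, drop = FALSE],
       eliminated = sol[idx, 5])
}

# adaptive 2-D Gauss-Hermite marginal -2LL for one subject (2*pi constants
# dropped, matching the package's OFV convention)
gh_ofv_subject <- function(sub_data, theta, ranef, model = flu_model(),
                           nodes = 30) {
  subs <- flupk:::parse_dataset(sub_data)
  s <- subs[[1]]
  typ <- flupk:::typical_matrix(model, theta, flupk:::covs_table(subs))
  Oinv <- solve(ranef$omega)
  ldo <- determinant(ranef$omega)$modulus[1]
  g <- function(e) {
    flupk:::cpp_g_subject(e, typ[1, ], s$doses, s$obs_t, s$logdv,
                          ranef$sigma, Oinv, ldo)
  }
  inner <- flupk:::cpp_inner_laplace(typ[1, ], s$doses, s$obs_t, s$logdv,
                                     ranef$sigma, ranef$omega, c(0, 0))
  eh <- inner$eta
  h <- 1e-4
  H <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) {
    ea <- c(0, 0); ea[a] <- h
    eb <- c(0, 0); eb[b] <- h
    H[a, b] <- (g(eh + ea + eb) - g(eh + ea - eb) -
                  g(eh - ea + eb) + g(eh - ea - eb)) / (4 * h^2)
  }
  A <- chol(solve(H / 2))
  gh <- pracma::gaussHermite(nodes)
  val <- 0
  for (i in seq_along(gh$x)) for (j in seq_along(gh$x)) {
    z <- sqrt(2) * c(gh$x[i], gh$x[j])
    e <- eh + as.numeric(t(A) %*% z)
    val <- val + gh$w[i] * gh$w[j] * exp(-g(e) / 2 + gh$x[i]^2 + gh$x[j]^2)
  }
  -2 * log(val * 2 * det(t(A)) / (2 * pi))
}

random_params <- function() {
  tibble::tibble(
    cl = runif(1, 2, 12), v1 = runif(1, 15, 70), v2 = runif(1, 5, 40),
    v3 = runif(1, 3, 40), cld2 = runif(1, 1, 12), cld3 = runif(1, 0.5, 8)
  )
}

random_regimen <- function(n_dose = sample(1:3, 1)) {
  tibble::tibble(
    start_time = sort(runif(n_dose, 0, 48)),
    amount = runif(n_dose, 10, 80),
    duration = runif(n_dose, 0.25, 2)
  )
}
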