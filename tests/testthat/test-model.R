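test_that("hazard is additive in x'beta", {
  grid <- seq(0.1, 10, length.out = 40)
  for (bl in baseline_grid()) {
    m <- ah_model(bl, beta = 0.8)
    expect_equal(ah_hazard(m, grid, x = 0), baseline_hazard(bl, grid),
                 tolerance = 1e-12)
    expect_equal(ah_hazard(m, grid, x = 1) - baseline_hazard(bl, grid),
                 rep(0.8, 40), tolerance = 1e-10)
  }
  # exponential baseline: constant overall hazard 1/1.77 + 0.84
  m <- ah_model(ah_baseline("exponential", 1.77), beta = 0.84)
  expect_equal(ah_hazard(m, 3.3, x = 1), 1 / 1.77 + 0.84, tolerance = 1e-12)
  # a strongly negative effect must be flagged, identifying the time
  mneg <- ah_model(ah_baseline("exponential", 1.77), beta = -2)
  expect_error(ah_hazard(mneg, 1, x = 1), "negative hazard")
})

test_that("survival matches the closed form and the hazard integral", {
  wb <- ah_baseline("weibull", c(0.86, 1.77))
  m <- ah_model(wb, beta = 0.8)
  expect_equal(ah_survival(m, 1, x = 1), exp(-(1 / 1.77)^0.86 - 0.8),
               tolerance = 1e-12)
  expect_equal(ah_survival(m, 0, x = 1), 1)
  grid <- seq(0.2, 4, length.out = 8)
  for (bl in baseline_grid()) {
    mm <- ah_model(bl, beta = 0.5)
    expect_equal(ah_survival(mm, grid, x = 0), baseline_survival(bl, grid),
                 tolerance = 1e-12)
    # S_x(t) = exp(-int_0^t h_x) by quadrature
    for (tt in c(0.7, 2.1)) {
      expect_equal(ah_survival(mm, tt, x = 1),
                   exp(-quad(function(u) ah_hazard(mm, u, x = 1), 0, tt)),
                   tolerance = 1e-6)
    }
    # -d/dt log S_x = h_x by central differences
    h <- 1e-5
    dlogS <- (log(ah_survival(mm, grid + h, 1)) -
                log(ah_survival(mm, grid - h, 1))) / (2 * h)
    expect_equal(-dlogS, ah_hazard(mm, grid, 1), tolerance = 1e-5)
  }
})

test_that("density equals hazard times survival and integrates to one", {
  grid <- seq(0.05, 12, length.out = 100)
  for (bl in baseline_grid()) {
    m <- ah_model(bl, beta = 0.8)
    expect_equal(ah_density(m, grid, x = 0), baseline_pdf(bl, grid),
                 tolerance = 1e-10)
    expect_equal(ah_density(m, grid, x = 1),
                 ah_hazard(m, grid, 1) * ah_survival(m, grid, 1),
                 tolerance = 1e-10)
  }
  m <- ah_model(ah_baseline("weibull", c(0.86, 1.77)), beta = 0.8)
  expect_equal(quad(function(u) ah_density(m, u, 1), 0, 100), 1,
               tolerance = 1e-6)
})

test_that("relative survival is exp(-t x beta) for every baseline family", {
  ts <- c(0, 0.5, 1, 2, 5)
  for (bl in baseline_grid()) {
    m <- ah_model(bl, beta = 0.8)
    rs <- relative_survival(m, ts, x = 1)
    # the defining ratio of survival functions, computed the long way
    expect_equal(rs, ah_survival(m, ts, 1) / baseline_survival(bl, ts),
                 tolerance = 1e-12)
    expect_equal(rs, exp(-0.8 * ts), tolerance = 1e-15)
    expect_identical(relative_survival(m, ts, x = 0), rep(1, length(ts)))
  }
})

test_that("log-likelihood matches per-term oracles", {
  # single uncensored observation, x = 0, exponential(scale b): log f0
  b <- 1.4; t1 <- 0.9
  d1 <- survival_data(t1, event = 1, x = 0)
  m1 <- ah_model(ah_baseline("exponential", b), beta = 0.3)
  expect_equal(ah_loglik(m1, d1), -log(b) - t1 / b, tolerance = 1e-12)
  # single censored observation, x = 0, weibull(a, b): log S0 = -(t/b)^a
  d2 <- survival_data(2.2, event = 0, x = 0)
  m2 <- ah_model(ah_baseline("weibull", c(0.86, 1.77)), beta = 0.3)
  expect_equal(ah_loglik(m2, d2), -(2.2 / 1.77)^0.86, tolerance = 1e-12)

  # mixed 5-record dataset against an independent per-term computation
  d <- toy_data()
  beta <- 0.6
  m <- ah_model(ah_baseline("weibull", c(0.86, 1.77)), beta = beta)
  expected <- 0
  for (i in seq_len(d$n)) {
    ti <- d$time[i]; xi <- d$x[i, 1]; di <- d$delta[i]
    S0 <- exp(-(ti / 1.77)^0.86)
    f0 <- stats::dweibull(ti, 0.86, 1.77)
    term <- if (di == 0) {
      log(f0 + xi * beta * S0) - ti * xi * beta
    } else {
      log(S0) - ti * xi * beta
    }
    expected <- expected + term
  }
  expect_equal(ah_loglik(m, d), unname(expected), tolerance = 1e-12)

  # at beta = 0 the likelihood splits into baseline pdf / survival terms
  m0 <- ah_model(ah_baseline("weibull", c(0.86, 1.77)), beta = 0)
  ev <- d$delta == 0
  expect_equal(ah_loglik(m0, d),
               sum(baseline_pdf(m0$baseline, d$time[ev], log = TRUE)) +
                 sum(baseline_survival(m0$baseline, d$time[!ev],
                                       log.p = TRUE)),
               tolerance = 1e-12)

  # infeasible parameters hit the sentinel, never NaN or an error
  m_bad <- ah_model(ah_baseline("weibull", c(0.86, 1.77)), beta = -50)
  expect_identical(ah_loglik(m_bad, d), -1e10)
})

test_that("numerical gradient of the log-likelihood matches the analytic one", {
  set.seed(42)
  d <- sim_dataset(sim_design("weibull", c(0.86, 1.77), beta = 0.8, n = 60,
                              event_fraction = 0.8))
  for (rep in 1:20) {
    a <- runif(1, 0.5, 2); b <- runif(1, 0.8, 3); beta <- runif(1, 0, 1.2)
    f <- function(p) ah_loglik(ah_model(ah_baseline("weibull", p[1:2]),
                                        p[3]), d)
    g_num <- num_grad(f, c(a, b, beta))
    g_ana <- weibull_loglik_gradient(a, b, beta, d)
    expect_equal(g_num, g_ana, tolerance = 1e-5)
  }
})
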