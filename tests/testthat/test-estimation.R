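# fake converged fit with known covariance, for interval arithmetic checks
fake_fit <- function(beta = 0.8, se = 0.1) {
  structure(list(family = "exponential", opt_scale = "log",
                 theta = c(scale = 1), beta = c(x = beta),
                 vcov = diag(c(0.04, se^2)), converged = TRUE,
                 ci_level = 0.95),
            class = "ah_fit")
}

test_that("Wald intervals are estimate +/- z * SE and nest across levels", {
  ci <- wald_intervals(fake_fit(), level = 0.95)
  b <- ci[ci$term == "beta.x", ]
  expect_equal(b$estimate, 0.8)
  expect_equal(round(b$lower, 3), 0.604)
  expect_equal(round(b$upper, 3), 0.996)
  ci50 <- wald_intervals(fake_fit(), level = 0.5)
  expect_true(all(ci50$lower > ci$lower & ci50$upper < ci$upper))
  # non-converged fits refuse to produce intervals
  bad <- fake_fit(); bad$converged <- FALSE
  expect_error(wald_intervals(bad), "unavailable")
})

test_that("input validation: empty, all-censored, bad start", {
  expect_error(ah_fit(survival_data(c(1, 2), c(0, 0), c(0, 1)), "weibull"),
               "censored")
  d <- sim_dataset(sim_design(n = 50), seed = 1)
  expect_error(ah_fit(d, "weibull", start = c(1, 1)), "length 3")
})

test_that("ML recovers generating parameters and sits at a stationary point", {
  d <- sim_dataset(sim_design("weibull", c(0.86, 1.77), beta = 0.8,
                              n = 4000, event_fraction = 1), seed = 7)
  f <- ah_fit(d, "weibull")
  expect_true(f$converged)
  expect_lt(abs(f$beta - 0.8), 3 * f$se_beta + 1e-8)
  expect_lt(abs(f$theta[["shape"]] - 0.86) / 0.86, 0.05)
  expect_lt(abs(f$theta[["scale"]] - 1.77) / 1.77, 0.05)
  # gradient of the mean log-likelihood vanishes at the optimum
  g <- num_grad(function(p) {
    ah_loglik(ah_model(ah_baseline("weibull", p[1:2]), p[3]), d)
  }, c(f$theta, f$beta))
  expect_lt(max(abs(g)) / d$n, 1e-4)
})

test_that("null effect: estimate near zero with interval covering zero", {
  d <- sim_dataset(sim_design("weibull", c(0.86, 1.77), beta = 0,
                              n = 4000, event_fraction = 1), seed = 8)
  f <- ah_fit(d, "weibull")
  expect_lt(abs(f$beta), 3 * f$se_beta)
  ci <- f$ci[f$ci$term == "beta.x", ]
  expect_true(ci$lower <= 0 && 0 <= ci$upper)
})

test_that("information criteria identities hold exactly for every family", {
  d <- sim_dataset(sim_design("weibull", c(0.86, 1.77), beta = 0.8,
                              n = 400, event_fraction = 0.8), seed = 9)
  cmp <- ah_compare(d)
  for (f in cmp$fits) {
    expect_equal(f$aic, -2 * f$loglik + 2 * f$k, tolerance = 1e-12)
    expect_equal(f$bic, -2 * f$loglik + f$k * log(f$n), tolerance = 1e-12)
    expect_equal(f$k, length(f$theta) + length(f$beta))
  }
})

test_that("refits from perturbed starting values reach the same optimum", {
  d <- sim_dataset(sim_design("weibull", c(0.86, 1.77), beta = 0.8,
                              n = 2000, event_fraction = 0.8), seed = 10)
  f0 <- ah_fit(d, "weibull", start = c(0.86, 1.77, 0.8))
  f1 <- ah_fit(d, "weibull", start = c(0.86, 1.77, 0.8) * 1.2)
  f2 <- ah_fit(d, "weibull", start = c(0.86, 1.77, 0.8) * 0.8)
  expect_lt(abs(f1$beta - f0$beta), 1e-4)
  expect_lt(abs(f2$beta - f0$beta), 1e-4)
  expect_lt(abs(f1$loglik - f0$loglik), 1e-6)
})

test_that("default starting values let every family converge", {
  d <- sim_dataset(sim_design("weibull", c(0.86, 1.77), beta = 0.8,
                              n = 1000, event_fraction = 0.8), seed = 11)
  for (fam in setdiff(ah_families(), "gompertz")) {
    f <- ah_fit(d, fam)
    expect_true(f$converged, label = paste("converged for", fam))
    expect_true(is.finite(f$bic))
  }
  # a Gompertz hazard cannot decrease, so on decreasing-hazard data its rate
  # is driven to the boundary; that must surface as a flag, not an error
  fg <- ah_fit(d, "gompertz")
  expect_s3_class(fg, "ah_fit")
  expect_true(is.finite(fg$loglik))
  # on data from an increasing-hazard truth it converges in the interior
  dg <- sim_dataset(sim_design("gompertz", c(0.4, 0.5), beta = 0.5,
                               n = 1000, event_fraction = 0.9), seed = 15)
  expect_true(ah_fit(dg, "gompertz")$converged)
})

test_that("model comparison ranks the generating family above log-normal", {
  d <- sim_dataset(sim_design("weibull", c(0.86, 1.77), beta = 0.8,
                              n = 5000, event_fraction = 0.8), seed = 12)
  cmp <- ah_compare(d, families = c("weibull", "lognormal"))
  tab <- cmp$table
  expect_lt(tab$bic[tab$family == "weibull"],
            tab$bic[tab$family == "lognormal"])
  # single-family comparison degenerates to a one-row table
  cmp1 <- ah_compare(d, families = "weibull")
  expect_identical(nrow(cmp1$table), 1L)
  expect_identical(cmp1$table$rank, 1L)
})

test_that("baseline summaries at the estimate match Table-style reporting", {
  # summaries evaluated at theta-hat equal the closed forms
  d <- sim_dataset(sim_design("loglogistic", c(1.06, 1.14), beta = 0.8,
                              n = 1500, event_fraction = 0.8), seed = 13)
  f <- ah_fit(d, "loglogistic")
  bs <- f$baseline_summary
  expect_equal(bs["median", "estimate"], f$theta[["scale"]],
               tolerance = 1e-10)
  expect_true(all(bs$available))
  expect_true(bs["median", "lower"] < bs["median", "estimate"])
  # nonexistent mean is reported as unavailable, not an error
  g <- f
  g$theta <- c(scale = 1.06, shape = 0.9)
  g$baseline <- ah_baseline("loglogistic", g$theta)
  bs2 <- baseline_summaries(g)
  expect_false(bs2["mean", "available"])
  expect_true(is.na(bs2["mean", "estimate"]))
})

test_that("delta-method SE of the baseline median agrees with a parametric bootstrap", {
  set.seed(14)
  d <- sim_dataset(sim_design("weibull", c(0.86, 1.77), beta = 0.8,
                              n = 800, event_fraction = 0.9))
  f <- ah_fit(d, "weibull")
  se_delta <- (f$baseline_summary["median", "upper"] -
                 f$baseline_summary["median", "estimate"]) / qnorm(0.975)
  boot <- replicate(200, {
    db <- sim_dataset(sim_design("weibull", f$theta, beta = f$beta[[1]],
                                 n = 800, event_fraction = 0.9))
    fb <- ah_fit(db, "weibull", start = c(f$theta, f$beta))
    if (fb$converged) baseline_median(fb$baseline) else NA_real_
  })
  se_boot <- sd(boot, na.rm = TRUE)
  expect_lt(abs(se_delta - se_boot) / se_boot, 0.15)
})
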