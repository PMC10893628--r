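# Shared fixtures and independent oracles used across the suite.

# one representative parameter set per baseline family
baseline_grid <- function() {
  list(
    exponential = ah_baseline("exponential", 1.77),
    weibull     = ah_baseline("weibull", c(0.86, 1.77)),
    gamma       = ah_baseline("gamma", c(1.3, 1.2)),
    gompertz    = ah_baseline("gompertz", c(0.4, 0.5)),
    lognormal   = ah_baseline("lognormal", c(0.1, 0.9)),
    loglogistic = ah_baseline("loglogistic", c(1.06, 1.14))
  )
}

# quadrature oracle, independent of the package's log-scale evaluation path
quad <- function(f, lower, upper, ...) {
  stats::integrate(f, lower, upper, rel.tol = 1e-10,
                   subdivisions = 500L, ...)$value
}

# analytic gradient of the additive-hazard log-likelihood for the Weibull
# baseline (natural parameters a, b, beta; single covariate), derived by
# hand from l_i = (1-d)[log S0 + log(h0 + x b) - t x b] + d[log S0 - t x b]
weibull_loglik_gradient <- function(a, b, beta, data) {
  t <- data$time
  x <- drop(data$x)
  d <- data$delta
  z <- (t / b)^a
  h0 <- (a / b) * (t / b)^(a - 1)
  dls_da <- -z * log(t / b)
  dls_db <- a * z / b
  dh0_da <- h0 * (1 / a + log(t / b))
  dh0_db <- -(a / b) * h0
  harg <- h0 + x * beta
  ev <- d == 0L
  g_a <- sum(dls_da + ifelse(ev, dh0_da / harg, 0))
  g_b <- sum(dls_db + ifelse(ev, dh0_db / harg, 0))
  g_beta <- sum(ifelse(ev, x / harg, 0) - t * x)
  c(g_a, g_b, g_beta)
}

# central-difference gradient of a scalar function
num_grad <- function(f, p, h = 1e-6) {
  vapply(seq_along(p), function(j) {
    hp <- h * max(1, abs(p[j]))
    e <- rep(0, length(p)); e[j] <- hp
    (f(p + e) - f(p - e)) / (2 * hp)
  }, numeric(1))
}

# small mixed survival dataset used in several oracle checks
toy_data <- function() {
  survival_data(time = c(0.5, 1.2, 0.8, 2.5, 0.3),
                event = c(1, 0, 1, 1, 0),
                x = c(0, 0, 1, 1, 1))
}

# additive-hazard cdf computed directly from the definition (Eq 5/6 form)
ah_cdf_direct <- function(baseline, beta, x, t) {
  1 - baseline_survival(baseline, t) * exp(-t * x * beta)
}
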