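## --- parameter transforms -------------------------------------------------
##
## Optimization runs unconstrained: strictly positive baseline parameters are
## log-transformed (every component except the lognormal location), beta is
## untouched. Covariances are reported on this optimization scale and mapped
## back where needed.

.theta_log_mask <- function(family) {
  if (family == "lognormal") c(FALSE, TRUE)
  else rep(TRUE, length(.theta_names[[family]]))
}

.theta_to_opt <- function(family, theta, opt_scale = "log") {
  if (opt_scale == "natural") return(theta)
  m <- .theta_log_mask(family)
  out <- theta
  out[m] <- log(theta[m])
  out
}

.theta_from_opt <- function(family, par, opt_scale = "log") {
  if (opt_scale == "natural") return(par)
  m <- .theta_log_mask(family)
  out <- par
  out[m] <- exp(par[m])
  out
}

## --- starting values ------------------------------------------------------

## censoring-naive moment / quantile match on the pooled observation times
.default_start <- function(data, family) {
  t <- data$time
  m <- mean(t); v <- stats::var(t)
  lt <- log(t); lm <- mean(lt); ls <- max(stats::sd(lt), 1e-3)
  med <- stats::median(t)
  theta <- switch(family,
    exponential = m,
    weibull     = {
      a <- min(max(pi / (sqrt(6) * ls), 0.05), 50)
      c(a, exp(lm + 0.5772156649 / a))
    },
    gamma       = c(max(m^2 / max(v, 1e-12), 0.05), max(v, 1e-12) / m),
    gompertz    = {
      b <- 1 / m
      c(max(b * log(2) / expm1(b * med), 1e-8), b)
    },
    lognormal   = c(lm, ls),
    loglogistic = c(med, min(max(pi / (sqrt(3) * ls), 0.05), 50)))
  c(theta, rep(0, ncol(data$x)))
}

## --- maximum-likelihood fit -----------------------------------------------

#' Fit a parametric additive hazard model by maximum likelihood
#'
#' Maximizes the censoring-aware log-likelihood of the additive hazard model
#' \eqn{h_x(t) = h_0(t) + x'\beta} jointly over the baseline parameters
#' \eqn{\theta} and the regression coefficients \eqn{\beta}, using
#' [stats::optim()] (BFGS, with a Nelder-Mead restart if the first pass does
#' not converge). Positive baseline parameters are optimized on the log
#' scale.
#'
#' Standard errors come from the inverse observed information (numerical
#' Hessian at the optimum) on the optimization scale. Confidence intervals
#' for \eqn{\beta} are Wald intervals on the natural scale; intervals for
#' \eqn{\theta} are Wald intervals on the optimization scale mapped back, so
#' they respect positivity. The derived baseline mean and median carry
#' delta-method intervals (see [baseline_summaries()]).
#'
#' A failed optimization or a non-invertible information matrix is reported
#' through `converged = FALSE`, never as an error, so simulation loops can
#' keep convergence bookkeeping.
#'
#' @param data A [survival_data()] object with at least one event.
#' @param family Baseline family, one of [ah_families()].
#' @param start Optional starting values `c(theta, beta)` on the natural
#'   scale (e.g. true values in a simulation protocol). Default: a
#'   censoring-naive moment/quantile match on the pooled times and
#'   `beta = 0`.
#' @param ci_level Confidence level for all reported intervals.
#' @param method Optimization protocol. `"transformed-bfgs"` (default)
#'   optimizes with BFGS on the log scale for positive baseline parameters,
#'   which enforces positivity and is the more robust general-purpose
#'   choice. `"natural-nm"` runs Nelder-Mead directly on the natural
#'   parameter scale with [stats::optim()]'s default settings - the classic
#'   hand-coded-likelihood protocol, used by the simulation-study harness
#'   ([run_setting()]) so its convergence behaviour matches that protocol.
#' @return An object of class `"ah_fit"`: the fitted [ah_model()] plus
#'   `theta`, `beta`, `se_beta`, `vcov` (optimization scale), `loglik`,
#'   `aic`, `bic`, `k`, `converged`, `n`, `n_events`, `ci` (data frame of
#'   natural-scale estimates and Wald limits) and the baseline mean/median
#'   summaries.
#' @seealso [ah_compare()] to fit several families and rank them by BIC;
#'   [lin_ying()] for the semi-parametric comparator.
#' @export
#' @examples
#' set.seed(1)
#' d <- sim_dataset(sim_design("weibull", c(0.86, 1.77), beta = 0.8,
#'                             n = 400, event_fraction = 0.8))
#' ah_fit(d, "weibull")
ah_fit <- function(data, family, start = NULL, ci_level = 0.95,
                   method = c("transformed-bfgs", "natural-nm")) {
  stopifnot(inherits(data, "survival_data"))
  family <- match.arg(family, ah_families())
  method <- match.arg(method)
  opt_scale <- if (method == "natural-nm") "natural" else "log"
  if (data$n == 0L) stop("empty dataset", call. = FALSE)
  if (all(data$delta == 1L)) {
    stop("all observations are censored; the model cannot be fitted",
         call. = FALSE)
  }
  k_theta <- length(.theta_names[[family]])
  p <- ncol(data$x)
  k <- k_theta + p
  if (data$n < k + 1L) stop("need at least k + 1 observations", call. = FALSE)

  if (is.null(start)) start <- .default_start(data, family)
  if (length(start) != k) {
    stop(sprintf("'start' must have length %d (theta then beta)", k),
         call. = FALSE)
  }
  par0 <- c(.theta_to_opt(family, start[seq_len(k_theta)], opt_scale),
            start[-seq_len(k_theta)])

  negll <- function(par) {
    theta <- .theta_from_opt(family, par[seq_len(k_theta)], opt_scale)
    if (any(!is.finite(theta))) return(-.LOGLIK_SENTINEL)
    bl <- tryCatch(ah_baseline(family, theta), error = function(e) NULL)
    if (is.null(bl)) return(-.LOGLIK_SENTINEL)
    -ah_loglik(ah_model(bl, par[-seq_len(k_theta)]), data)
  }

  if (method == "natural-nm") {
    opt <- tryCatch(stats::optim(par0, negll, method = "Nelder-Mead"),
                    error = function(e) NULL)
  } else {
    opt <- tryCatch(
      stats::optim(par0, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$convergence != 0) {
      nm <- tryCatch(
        stats::optim(opt$par, negll, method = "Nelder-Mead",
                     control = list(maxit = 2000)),
        error = function(e) NULL)
      if (!is.null(nm) && nm$value <= opt$value) opt <- nm
    }
  }

  converged <- !is.null(opt) && opt$convergence == 0 &&
    opt$value < -.LOGLIK_SENTINEL / 2
  if (is.null(opt)) {
    opt <- list(par = par0, value = -.LOGLIK_SENTINEL, convergence = 1L)
  }

  vcov <- matrix(NA_real_, k, k)
  if (converged) {
    H <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) <= 0)) {
      converged <- FALSE
    } else {
      vcov <- V
    }
  }

  theta_hat <- .theta_from_opt(family, opt$par[seq_len(k_theta)], opt_scale)
  names(theta_hat) <- .theta_names[[family]]
  beta_hat <- opt$par[-seq_len(k_theta)]
  names(beta_hat) <- colnames(data$x)
  loglik <- -opt$value
  dn <- c(paste0("theta.", names(theta_hat)), paste0("beta.", names(beta_hat)))
  dimnames(vcov) <- list(dn, dn)

  fit <- structure(list(
    family = family,
    method = method,
    opt_scale = opt_scale,
    baseline = ah_baseline(family, theta_hat),
    theta = theta_hat,
    beta = beta_hat,
    se_beta = sqrt(diag(vcov)[k_theta + seq_len(p)]),
    vcov = vcov,
    loglik = loglik,
    k = k,
    aic = -2 * loglik + 2 * k,
    bic = -2 * loglik + k * log(data$n),
    converged = converged,
    n = data$n,
    n_events = sum(data$delta == 0L),
    ci_level = ci_level,
    start = start
  ), class = "ah_fit")
  ## assign via list() so a NULL (failed) result keeps the element present
  ## instead of deleting it (which would let $ci partial-match ci_level)
  fit["ci"] <- list(tryCatch(wald_intervals(fit, ci_level),
                             error = function(e) NULL))
  fit["baseline_summary"] <- list(tryCatch(baseline_summaries(fit, ci_level),
                                           error = function(e) NULL))
  fit
}

#' Wald confidence intervals for an additive hazard fit
#'
#' Intervals are `estimate +/- z * SE`: on the natural scale for the
#' regression coefficients, and on the (log-transformed) optimization scale
#' for the positive baseline parameters, then mapped back through `exp` so
#' the reported limits respect positivity.
#'
#' @param fit An [ah_fit()] object with `converged = TRUE`.
#' @param level Confidence level.
#' @return Data frame with columns `term`, `estimate`, `lower`, `upper`.
#' @export
wald_intervals <- function(fit, level = fit$ci_level) {
  stopifnot(inherits(fit, "ah_fit"))
  if (!fit$converged || any(!is.finite(diag(fit$vcov)))) {
    stop("intervals unavailable: fit did not converge or information matrix is singular",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  k_theta <- length(fit$theta)
  se <- sqrt(diag(fit$vcov))
  mask <- .theta_log_mask(fit$family) & fit$opt_scale == "log"
  par_opt <- c(.theta_to_opt(fit$family, fit$theta, fit$opt_scale), fit$beta)
  lo <- par_opt - z * se
  hi <- par_opt + z * se
  est <- c(fit$theta, fit$beta)
  for (j in seq_len(k_theta)) {
    if (mask[j]) { lo[j] <- exp(lo[j]); hi[j] <- exp(hi[j]) }
  }
  data.frame(
    term = c(paste0("theta.", names(fit$theta)),
             paste0("beta.", names(fit$beta))),
    estimate = unname(est), lower = unname(lo), upper = unname(hi),
    row.names = NULL)
}

#' @export
confint.ah_fit <- function(object, parm, level = 0.95, ...) {
  ci <- wald_intervals(object, level)
  out <- as.matrix(ci[, c("lower", "upper")])
  rownames(out) <- ci$term
  colnames(out) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                trim = TRUE), "%")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
logLik.ah_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
nobs.ah_fit <- function(object, ...) object$n

#' Baseline mean and median of a fit, with delta-method intervals
#'
#' Evaluates [baseline_mean()] and [baseline_median()] at the fitted
#' \eqn{\hat\theta} and propagates uncertainty by the delta method: the
#' gradient of each summary with respect to the optimization-scale baseline
#' parameters is computed numerically and combined with the corresponding
#' block of the fitted covariance. Intervals are symmetric on the natural
#' scale of the summary.
#'
#' A summary that does not exist (log-logistic mean with shape \eqn{\le 1})
#' is reported as `NA` with `available = FALSE`, mirroring the "-" cells of
#' a model-comparison table.
#'
#' @param fit A converged [ah_fit()] object.
#' @param level Confidence level.
#' @return Data frame with rows `mean` and `median` and columns `estimate`,
#'   `lower`, `upper`, `available`.
#' @export
baseline_summaries <- function(fit, level = fit$ci_level) {
  stopifnot(inherits(fit, "ah_fit"))
  k_theta <- length(fit$theta)
  Vth <- fit$vcov[seq_len(k_theta), seq_len(k_theta), drop = FALSE]
  z <- stats::qnorm(1 - (1 - level) / 2)
  par_opt <- .theta_to_opt(fit$family, fit$theta, fit$opt_scale)

  one <- function(summary_fun) {
    est <- tryCatch(
      as.numeric(summary_fun(ah_baseline(fit$family, fit$theta))),
      error = function(e) NA_real_)
    if (!is.finite(est)) {
      return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
    }
    se <- NA_real_
    if (fit$converged && all(is.finite(Vth))) {
      g <- tryCatch(pracma::grad(function(p) {
        as.numeric(summary_fun(
          ah_baseline(fit$family,
                      .theta_from_opt(fit$family, p, fit$opt_scale))))
      }, par_opt), error = function(e) NULL)
      if (!is.null(g) && all(is.finite(g))) {
        se <- sqrt(drop(t(g) %*% Vth %*% g))
      }
    }
    c(estimate = est, lower = est - z * se, upper = est + z * se)
  }

  m <- one(baseline_mean)
  md <- one(baseline_median)
  out <- as.data.frame(rbind(mean = m, median = md))
  out$available <- is.finite(out$estimate)
  out
}

#' @export
print.ah_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Parametric additive hazard model (%s baseline)\n", x$family))
  cat(sprintf("N = %d (%d events), logLik = %.2f, AIC = %.1f, BIC = %.1f, converged: %s\n",
              x$n, x$n_events, x$loglik, x$aic, x$bic, x$converged))
  if (!is.null(x$ci)) {
    ci <- x$ci
    cat(sprintf("Estimates with %g%% Wald confidence intervals:\n",
                100 * x$ci_level))
    for (i in seq_len(nrow(ci))) {
      cat(sprintf("  %-16s %8.*f  [%.*f; %.*f]\n", ci$term[i],
                  digits, ci$estimate[i], digits, ci$lower[i],
                  digits, ci$upper[i]))
    }
  } else {
    cat("  theta:", format(x$theta, digits = digits), "\n")
    cat("  beta: ", format(x$beta, digits = digits), "\n")
  }
  if (!is.null(x$baseline_summary)) {
    bs <- x$baseline_summary
    fmt <- function(r) {
      if (!bs[r, "available"]) return("-")
      sprintf("%.*f [%.*f; %.*f]", digits, bs[r, "estimate"],
              digits, bs[r, "lower"], digits, bs[r, "upper"])
    }
    cat("  baseline mean:  ", fmt("mean"), "\n")
    cat("  baseline median:", fmt("median"), "\n")
  }
  invisible(x)
}

## --- multi-family comparison ----------------------------------------------

#' Fit several baseline families and rank them by BIC
#'
#' Fits one additive hazard model per requested family and assembles a
#' comparison table (coefficients with intervals, baseline mean and median,
#' number of distribution parameters, BIC) sorted by BIC ascending; ties are
#' broken by fewer parameters, then family name. Families whose fit fails
#' are kept in the output with `converged = FALSE` rather than aborting the
#' comparison.
#'
#' @param data A [survival_data()] object.
#' @param families Character vector of families, default all six.
#' @param ci_level Confidence level for the per-family intervals.
#' @param start Optional named list of per-family starting values.
#' @return An object of class `"ah_comparison"`: list with `fits` (named
#'   list of [ah_fit()] objects) and `table` (the ranked data frame).
#' @export
ah_compare <- function(data, families = ah_families(), ci_level = 0.95,
                       start = NULL) {
  families <- match.arg(families, ah_families(), several.ok = TRUE)
  fits <- lapply(families, function(fam) {
    st <- if (!is.null(start)) start[[fam]]
    tryCatch(ah_fit(data, fam, start = st, ci_level = ci_level),
             error = function(e) {
               structure(list(family = fam, converged = FALSE,
                              error = conditionMessage(e)),
                         class = "ah_fit_failure")
             })
  })
  names(fits) <- families

  rows <- lapply(fits, function(f) {
    if (inherits(f, "ah_fit_failure")) {
      return(data.frame(family = f$family, beta = NA_real_,
                        beta_lower = NA_real_, beta_upper = NA_real_,
                        baseline_mean = NA_real_, mean_lower = NA_real_,
                        mean_upper = NA_real_, baseline_median = NA_real_,
                        median_lower = NA_real_, median_upper = NA_real_,
                        n_params = NA_integer_, bic = Inf,
                        converged = FALSE))
    }
    bs <- f[["baseline_summary"]]
    ci <- f[["ci"]]
    bi <- if (!is.null(ci)) grep("^beta\\.", ci$term)[1L] else NA_integer_
    data.frame(
      family = f$family,
      beta = f$beta[[1L]],
      beta_lower = if (!is.null(ci)) ci$lower[bi] else NA_real_,
      beta_upper = if (!is.null(ci)) ci$upper[bi] else NA_real_,
      baseline_mean = if (!is.null(bs)) bs["mean", "estimate"] else NA_real_,
      mean_lower = if (!is.null(bs)) bs["mean", "lower"] else NA_real_,
      mean_upper = if (!is.null(bs)) bs["mean", "upper"] else NA_real_,
      baseline_median = if (!is.null(bs)) bs["median", "estimate"] else NA_real_,
      median_lower = if (!is.null(bs)) bs["median", "lower"] else NA_real_,
      median_upper = if (!is.null(bs)) bs["median", "upper"] else NA_real_,
      n_params = length(f$theta),
      bic = f$bic,
      converged = f$converged)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$bic, tab$n_params, tab$family)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab), class = "ah_comparison")
}

#' @export
print.ah_comparison <- function(x, digits = 2, ...) {
  tab <- x$table
  fmt <- function(est, lo, hi) {
    ifelse(is.finite(est),
           sprintf("%.*f [%.*f; %.*f]", digits, est, digits, lo, digits, hi),
           "-")
  }
  out <- data.frame(
    Distribution = tab$family,
    beta = fmt(tab$beta, tab$beta_lower, tab$beta_upper),
    `Baseline Mean` = fmt(tab$baseline_mean, tab$mean_lower, tab$mean_upper),
    `Baseline Median` = fmt(tab$baseline_median, tab$median_lower,
                            tab$median_upper),
    `No. params` = tab$n_params,
    BIC = sprintf("%.1f", tab$bic),
    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}
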