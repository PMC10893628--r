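#' Right-censored survival dataset
#'
#' Container for right-censored time-to-event data: one row per subject with
#' an observation time, an event indicator and a (possibly multi-column)
#' covariate matrix.
#'
#' The public convention is `event = 1` for an observed event and `event = 0`
#' for a censored observation, as in [survival::Surv()]. Internally the
#' object stores the censoring indicator `delta = 1 - event` (`delta = 1`
#' meaning censored), which is the convention the model's log-likelihood is
#' written in; [as.data.frame.survival_data()] converts back to the public
#' `event` coding.
#'
#' @param time Positive observation times (same unit as the baseline
#'   distribution; years in the lung-cancer example).
#' @param event Binary event indicator, 1 = event observed, 0 = censored.
#' @param x Covariate vector or matrix (one column per covariate), no
#'   missing values.
#' @return An object of class `"survival_data"` with elements `time`,
#'   `delta`, `x` (matrix) and `n`.
#' @export
#' @examples
#' d <- survival_data(c(1.2, 0.4, 2.1), event = c(1, 0, 1), x = c(0, 1, 1))
#' d
survival_data <- function(time, event, x) {
  time <- as.numeric(time)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("all observation times must be finite and > 0", call. = FALSE)
  }
  event <- as.integer(event)
  if (length(event) != length(time) || any(is.na(event)) ||
      any(!event %in% c(0L, 1L))) {
    stop("'event' must be a 0/1 vector matching 'time'", call. = FALSE)
  }
  x <- as.matrix(x)
  if (nrow(x) != length(time)) {
    stop("covariate rows must match the number of times", call. = FALSE)
  }
  if (any(is.na(x))) {
    stop("covariates must not contain missing values", call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) {
    colnames(x) <- if (ncol(x) == 1L) "x" else paste0("x", seq_len(ncol(x)))
  }
  structure(list(time = time, delta = 1L - event, x = x, n = length(time)),
            class = "survival_data")
}

#' @export
print.survival_data <- function(x, ...) {
  cat(sprintf("Survival dataset: %d subjects, %d events, %d censored, %d covariate(s)\n",
              x$n, sum(x$delta == 0L), sum(x$delta == 1L), ncol(x$x)))
  invisible(x)
}

#' @export
as.data.frame.survival_data <- function(x, ...) {
  data.frame(time = x$time, event = 1L - x$delta, x$x, check.names = FALSE)
}

#' Parametric additive hazard model
#'
#' Combines a baseline distribution with regression coefficients `beta` into
#' the additive hazard model \eqn{h_x(t) = h_0(t) + x'\beta}: covariates
#' shift the hazard by an additive amount rather than multiplying it.
#'
#' @param baseline An [ah_baseline()] object.
#' @param beta Numeric coefficient vector, one entry per covariate.
#' @return An object of class `"ah_model"`.
#' @export
#' @examples
#' m <- ah_model(ah_baseline("weibull", c(0.86, 1.77)), beta = 0.8)
#' ah_hazard(m, t = 1, x = 1)
ah_model <- function(baseline, beta) {
  stopifnot(inherits(baseline, "ah_baseline"))
  beta <- as.numeric(beta)
  if (length(beta) < 1L || any(!is.finite(beta))) {
    stop("'beta' must be a finite numeric vector", call. = FALSE)
  }
  structure(list(baseline = baseline, beta = beta), class = "ah_model")
}

#' @export
print.ah_model <- function(x, ...) {
  cat("Additive hazard model: h_x(t) = h_0(t) + x'beta\n")
  print(x$baseline)
  cat("beta:", format(x$beta), "\n")
  invisible(x)
}

## x'beta for a single covariate vector or an n x p matrix, recycled against t
.xbeta <- function(model, x) {
  p <- length(model$beta)
  if (is.matrix(x)) {
    if (ncol(x) != p) stop("covariate columns must match length(beta)",
                           call. = FALSE)
    drop(x %*% model$beta)
  } else {
    if (length(x) != p) stop("covariate vector must match length(beta)",
                             call. = FALSE)
    sum(x * model$beta)
  }
}

#' Hazard, survival, density and relative survival of the additive model
#'
#' The model's defining identities:
#' \deqn{h_x(t) = h_0(t) + x'\beta}
#' \deqn{S_x(t) = S_0(t) / \exp(t\, x'\beta)}
#' \deqn{f_x(t) = (f_0(t) + x'\beta\, S_0(t)) / \exp(t\, x'\beta)
#'             = h_x(t)\, S_x(t)}
#' \deqn{S_x(t)/S_0(t) = 1/\exp(t\, x'\beta)}
#' The last ratio is the relative survival of group `x` versus the baseline
#' group; it does not depend on the baseline family.
#'
#' A parameter/covariate combination that makes the hazard negative at some
#' requested time is rejected with an error identifying the offending time,
#' since the model is invalid there.
#'
#' @param model An [ah_model()] object.
#' @param t Time(s).
#' @param x Covariate vector (length `length(beta)`).
#' @return Numeric vector the length of `t`.
#' @export
ah_hazard <- function(model, t, x) {
  stopifnot(inherits(model, "ah_model"))
  .check_time(t, positive = TRUE)
  h <- baseline_hazard(model$baseline, t) + .xbeta(model, x)
  if (any(h < 0)) {
    stop(sprintf("negative hazard at t = %g for x'beta = %g",
                 t[which(h < 0)[1L]], .xbeta(model, x)), call. = FALSE)
  }
  h
}

#' @rdname ah_hazard
#' @export
ah_survival <- function(model, t, x) {
  stopifnot(inherits(model, "ah_model"))
  .check_time(t)
  exp(.baseline_logsurv(model$baseline, t) - t * .xbeta(model, x))
}

#' @rdname ah_hazard
#' @export
ah_density <- function(model, t, x) {
  stopifnot(inherits(model, "ah_model"))
  .check_time(t, positive = TRUE)
  xb <- .xbeta(model, x)
  h0 <- baseline_hazard(model$baseline, t)
  if (any(h0 + xb < 0)) {
    stop(sprintf("negative hazard at t = %g for x'beta = %g",
                 t[which(h0 + xb < 0)[1L]], xb), call. = FALSE)
  }
  ## f_x = h_x * S_x, assembled on the log scale from f0 = h0 * S0
  (h0 + xb) * exp(.baseline_logsurv(model$baseline, t) - t * xb)
}

#' @rdname ah_hazard
#' @export
relative_survival <- function(model, t, x) {
  stopifnot(inherits(model, "ah_model"))
  .check_time(t)
  exp(-t * .xbeta(model, x))
}

#' Log-likelihood of an additive hazard model
#'
#' Censoring-aware log-likelihood for right-censored data. With censoring
#' indicator \eqn{\delta_i} (1 = censored), subject \eqn{i} contributes
#' \deqn{\ell_i = (1-\delta_i)\left[\log(f_0(t_i) + x_i'\beta\, S_0(t_i))
#'   - t_i x_i'\beta\right] + \delta_i\left[\log S_0(t_i)
#'   - t_i x_i'\beta\right],}
#' i.e. events contribute the log pdf and censored observations the log
#' survival. The event term is computed as
#' \eqn{\log S_0(t_i) + \log(h_0(t_i) + x_i'\beta) - t_i x_i'\beta} for
#' numerical stability.
#'
#' Parameter values that make the hazard non-positive at any observed time
#' do not define a valid model there; for those the function returns the
#' finite sentinel `-1e10` (a stand-in for \eqn{-\infty} that derivative-based
#' optimizers can retreat from) rather than `NaN` or an error.
#'
#' @param model An [ah_model()] object.
#' @param data A [survival_data()] object.
#' @return The scalar log-likelihood, or `-1e10` when the parameters are
#'   infeasible for the data.
#' @export
ah_loglik <- function(model, data) {
  stopifnot(inherits(model, "ah_model"), inherits(data, "survival_data"))
  xb <- drop(data$x %*% model$beta)
  lh0 <- suppressWarnings(baseline_hazard(model$baseline, data$time,
                                          log = TRUE))
  harg <- exp(lh0) + xb
  if (anyNA(harg) || any(harg <= 0)) {
    return(.LOGLIK_SENTINEL)
  }
  ls0 <- suppressWarnings(.baseline_logsurv(model$baseline, data$time))
  ll <- ifelse(data$delta == 0L, ls0 + log(harg) - data$time * xb,
               ls0 - data$time * xb)
  out <- sum(ll)
  if (!is.finite(out)) .LOGLIK_SENTINEL else out
}

.LOGLIK_SENTINEL <- -1e10
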