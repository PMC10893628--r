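## canonical truth parameters of the two data-generating families; these are
## the lung-cancer-cohort estimates that define the study conditions and also
## serve as the "true value" starting points of the fitting protocol
.truth_theta <- list(weibull = c(0.86, 1.77), loglogistic = c(1.06, 1.14))
.truth_label <- c(weibull = "WBAH", loglogistic = "LLAH")

#' Factorial grid of simulation settings
#'
#' The full study grid crosses two truth families (Weibull, log-logistic
#' additive hazard: WBAH, LLAH), three true effects
#' \eqn{\beta \in \{0, 0.8, 1.6\}}, two study sizes \eqn{n \in \{50, 200\}}
#' and two event fractions \eqn{\{0.6, 0.8\}} - 24 settings in all. Setting
#' ids follow the `truth_beta_n_eventfraction` scheme, e.g.
#' `"WBAH_0_50_0.6"`.
#'
#' @return Data frame with columns `id`, `truth_family`, `beta_true`, `n`,
#'   `event_fraction`.
#' @export
#' @examples
#' nrow(sim_settings())  # 24
sim_settings <- function() {
  grid <- expand.grid(event_fraction = c(0.6, 0.8), n = c(50L, 200L),
                      beta_true = c(0, 0.8, 1.6),
                      truth_family = c("weibull", "loglogistic"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("truth_family", "beta_true", "n", "event_fraction")]
  grid$id <- sprintf("%s_%s_%d_%s", .truth_label[grid$truth_family],
                     format(grid$beta_true, trim = TRUE, drop0trailing = TRUE),
                     grid$n,
                     format(grid$event_fraction, trim = TRUE))
  grid[, c("id", "truth_family", "beta_true", "n", "event_fraction")]
}

## deterministic 32-bit seed for (master seed, setting id, replicate)
.replicate_seed <- function(master_seed, setting_id, replicate) {
  h <- 0
  for (ch in utf8ToInt(setting_id)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(master_seed) * 1009 + h * 97 + replicate) %% 2147480009)
}

#' Monte-Carlo performance metrics of an estimator
#'
#' Given replicate estimates and standard errors, computes the per-setting
#' summaries: bias aggregated by mean and by median
#' (\eqn{\hat\beta_k - \beta_{true}}), mean squared error, and empirical
#' coverage of nominal Wald intervals
#' \eqn{\hat\beta_k \pm z_{1-\alpha/2} SE_k} (an interval touching the truth
#' at an endpoint counts as covering).
#'
#' @param estimates Replicate point estimates.
#' @param ses Matching standard errors.
#' @param beta_true True parameter value.
#' @param ci_level Nominal interval level for the coverage summary.
#' @return Named list: `bias_mean`, `bias_median`, `mse`, `coverage`, `n`.
#' @export
#' @examples
#' summarize_metrics(c(0.6, 1.0, 1.4), c(0.2, 0.2, 0.2), beta_true = 1)
summarize_metrics <- function(estimates, ses, beta_true, ci_level = 0.95) {
  if (length(estimates) != length(ses)) {
    stop("'estimates' and 'ses' must have equal length", call. = FALSE)
  }
  ok <- is.finite(estimates) & is.finite(ses)
  estimates <- estimates[ok]; ses <- ses[ok]
  if (length(estimates) == 0L) {
    stop("no (finite) replicate estimates to summarize", call. = FALSE)
  }
  err <- estimates - beta_true
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  covered <- (estimates - z * ses <= beta_true) &
             (beta_true <= estimates + z * ses)
  list(bias_mean = mean(err), bias_median = stats::median(err),
       mse = mean(err^2), coverage = mean(covered), n = length(estimates))
}

#' Run one simulation setting
#'
#' Generates `replicates` datasets from the setting's truth model and fits
#' each requested estimator. Parametric estimators follow the study
#' protocol: Nelder-Mead on the natural parameter scale
#' (`method = "natural-nm"` in [ah_fit()]), started at the truth protocol
#' values (the canonical \eqn{\theta} of the estimating family and the
#' setting's true \eqn{\beta}). Replicates where an estimator does not
#' converge are excluded from its bias/MSE/coverage summaries but counted in
#' the convergence bookkeeping.
#'
#' @param setting One row of [sim_settings()] (or a one-row data frame with
#'   the same columns).
#' @param estimators Subset of `"weibull"`, `"loglogistic"`, `"lin_ying"`.
#' @param replicates Number of replicate datasets.
#' @param master_seed Integer master seed; each replicate derives its own
#'   seed from `(master_seed, setting id, replicate index)` so any single
#'   replicate is reproducible in isolation.
#' @return An object of class `"sim_setting_result"`: `setting`, `summary`
#'   (one row per estimator with bias/MSE/coverage/convergence) and `draws`
#'   (per-estimator matrices of replicate estimates, SEs and convergence
#'   flags).
#' @export
run_setting <- function(setting,
                        estimators = c("weibull", "loglogistic", "lin_ying"),
                        replicates = 1000, master_seed = 1) {
  setting <- as.list(as.data.frame(setting)[1L, ])
  estimators <- match.arg(estimators,
                          c("weibull", "loglogistic", "lin_ying"),
                          several.ok = TRUE)
  design <- sim_design(setting$truth_family,
                       .truth_theta[[setting$truth_family]],
                       beta = setting$beta_true, n = setting$n,
                       event_fraction = setting$event_fraction)
  draws <- lapply(estimators, function(e) {
    matrix(NA_real_, replicates, 3L,
           dimnames = list(NULL, c("beta", "se", "converged")))
  })
  names(draws) <- estimators

  for (r in seq_len(replicates)) {
    d <- sim_dataset(design,
                     seed = .replicate_seed(master_seed, setting$id, r))
    for (e in estimators) {
      if (e == "lin_ying") {
        f <- tryCatch(lin_ying(d), error = function(err) NULL)
        if (!is.null(f) && f$converged) {
          draws[[e]][r, ] <- c(f$beta[[1L]], f$se[[1L]], 1)
        } else {
          draws[[e]][r, "converged"] <- 0
        }
      } else {
        st <- c(.truth_theta[[e]], setting$beta_true)
        f <- tryCatch(ah_fit(d, e, start = st, method = "natural-nm"),
                      error = function(err) NULL)
        if (!is.null(f) && f$converged && all(is.finite(f$se_beta))) {
          draws[[e]][r, ] <- c(f$beta[[1L]], f$se_beta[[1L]], 1)
        } else {
          draws[[e]][r, "converged"] <- 0
        }
      }
    }
  }

  summary <- do.call(rbind, lapply(estimators, function(e) {
    m <- draws[[e]]
    conv <- m[, "converged"] == 1
    met <- if (any(conv)) {
      summarize_metrics(m[conv, "beta"], m[conv, "se"], setting$beta_true)
    } else {
      list(bias_mean = NA_real_, bias_median = NA_real_, mse = NA_real_,
           coverage = NA_real_, n = 0L)
    }
    data.frame(setting_id = setting$id, estimator = e,
               bias_mean = met$bias_mean, bias_median = met$bias_median,
               mse = met$mse, coverage = met$coverage,
               n_converged = sum(conv), replicates = replicates)
  }))
  rownames(summary) <- NULL
  structure(list(setting = setting, summary = summary, draws = draws),
            class = "sim_setting_result")
}

#' @export
print.sim_setting_result <- function(x, ...) {
  cat(sprintf("Simulation setting %s (%d replicates)\n", x$setting$id,
              x$summary$replicates[1L]))
  print(x$summary[, setdiff(names(x$summary), "setting_id")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the full (or a reduced) simulation study
#'
#' Iterates [run_setting()] over a grid of settings and stacks the
#' summaries, also providing the long-format `(setting_id, estimator,
#' metric, value)` table used for reporting. Deterministic given
#' `master_seed`.
#'
#' @param settings Data frame of settings, default the full 24-setting grid
#'   from [sim_settings()].
#' @param estimators Estimators to run, as in [run_setting()].
#' @param replicates Replicates per setting (the full study uses 1000).
#' @param master_seed Integer master seed.
#' @param verbose Print a progress line per setting to standard error.
#' @return An object of class `"sim_study_result"` with `summaries` (wide,
#'   one row per setting x estimator) and `long` (metric-per-row table).
#' @export
run_sim_study <- function(settings = sim_settings(),
                          estimators = c("weibull", "loglogistic", "lin_ying"),
                          replicates = 1000, master_seed = 1,
                          verbose = FALSE) {
  res <- lapply(seq_len(nrow(settings)), function(i) {
    if (verbose) {
      message(sprintf("[%d/%d] %s", i, nrow(settings), settings$id[i]))
    }
    run_setting(settings[i, ], estimators = estimators,
                replicates = replicates, master_seed = master_seed)
  })
  summaries <- do.call(rbind, lapply(res, `[[`, "summary"))
  metrics <- c("bias_mean", "bias_median", "mse", "coverage", "n_converged")
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(setting_id = summaries$setting_id,
               estimator = summaries$estimator, metric = m,
               value = summaries[[m]])
  }))
  rownames(long) <- NULL
  structure(list(summaries = summaries, long = long, results = res),
            class = "sim_study_result")
}

#' @export
print.sim_study_result <- function(x, ...) {
  cat(sprintf("Simulation study: %d settings x %d replicates\n",
              length(unique(x$summaries$setting_id)),
              x$summaries$replicates[1L]))
  print(x$summaries, row.names = FALSE, digits = 4)
  invisible(x)
}
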