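#' Read right-censored survival data from a delimited text file
#'
#' Reads a header-ed delimited file with one row per subject and builds a
#' [survival_data()] object. The file uses the public event coding
#' (`event = 1` means the event was observed); the censoring-indicator
#' convention used internally by the likelihood is handled by the
#' constructor. Rows with missing covariate values are dropped and the
#' count is reported, so a partially recorded predictor reduces the
#' analyzable sample explicitly rather than silently.
#'
#' @param path File path.
#' @param time_col,event_col Column names for the observation time and the
#'   0/1 event indicator.
#' @param covariate_cols Character vector of covariate column names;
#'   default: every other column.
#' @param sep Field separator (comma by default).
#' @return A [survival_data()] object.
#' @export
read_survival_data <- function(path, time_col = "time", event_col = "event",
                               covariate_cols = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(time_col, event_col, covariate_cols)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(covariate_cols)) {
    covariate_cols <- setdiff(names(df), c(time_col, event_col))
  }
  if (length(covariate_cols) == 0L) {
    stop("no covariate columns found", call. = FALSE)
  }
  time <- suppressWarnings(as.numeric(df[[time_col]]))
  if (any(is.na(time))) stop("non-numeric or missing times", call. = FALSE)
  event <- df[[event_col]]
  xs <- df[covariate_cols]
  if (any(vapply(xs, function(v) all(is.na(v)), logical(1)))) {
    stop("a covariate column is entirely missing", call. = FALSE)
  }
  keep <- stats::complete.cases(xs)
  if (any(!keep)) {
    message(sprintf("dropped %d row(s) with missing covariate values",
                    sum(!keep)))
  }
  survival_data(time[keep], event[keep],
                as.matrix(as.data.frame(lapply(xs, as.numeric)))[keep, ,
                                                                 drop = FALSE])
}

#' Write a survival dataset to a delimited text file
#'
#' Emits a header-ed file `time,event,<covariates>` with `event = 1` meaning
#' an observed event. Values are written with full double precision, so a
#' write/read round trip is lossless to at least 12 significant digits.
#'
#' @param data A [survival_data()] object.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_survival_data <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "survival_data"))
  df <- as.data.frame(data)
  df$time <- format(df$time, digits = 17, trim = TRUE, scientific = FALSE)
  for (nm in colnames(data$x)) {
    df[[nm]] <- format(df[[nm]], digits = 17, trim = TRUE,
                       scientific = FALSE)
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Kaplan-Meier estimates per covariate group
#'
#' Product-limit survival estimates (via [survival::survfit()]) for overlay
#' against fitted parametric curves, plus the empirical median survival time
#' per group. Groups without any event are skipped with a warning.
#'
#' @param data A [survival_data()] object.
#' @param group Optional name of a covariate column to stratify by;
#'   default: pooled estimate.
#' @return An object of class `"km_estimate"`: list with `curves` (named
#'   list of data frames `time`, `n_risk`, `n_event`, `surv`) and `median`
#'   (named vector of group medians, `NA` when the curve never reaches 0.5).
#' @export
kaplan_meier <- function(data, group = NULL) {
  stopifnot(inherits(data, "survival_data"))
  event <- 1L - data$delta
  if (is.null(group)) {
    g <- factor(rep("all", data$n))
  } else {
    if (!group %in% colnames(data$x)) {
      stop(sprintf("no covariate column '%s'", group), call. = FALSE)
    }
    g <- factor(data$x[, group])
  }
  curves <- list()
  medians <- numeric(0)
  for (lev in levels(g)) {
    idx <- g == lev
    if (sum(event[idx]) == 0L) {
      warning(sprintf("group '%s' has no events; skipped", lev))
      next
    }
    sf <- survival::survfit(
      survival::Surv(data$time[idx], event[idx]) ~ 1)
    curves[[lev]] <- data.frame(time = sf$time, n_risk = sf$n.risk,
                                n_event = sf$n.event, surv = sf$surv)
    med <- unname(stats::quantile(sf, probs = 0.5)$quantile)
    medians[lev] <- med
  }
  structure(list(curves = curves, median = medians), class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate(s)\n")
  for (lev in names(x$curves)) {
    cat(sprintf("  group %s: %d distinct times, median survival %s\n", lev,
                nrow(x$curves[[lev]]),
                ifelse(is.na(x$median[lev]), "not reached",
                       format(x$median[lev], digits = 4))))
  }
  invisible(x)
}

#' Relative survival curve from a fitted additive hazard model
#'
#' The model's relative survival for covariate profile `x` is
#' \eqn{\exp(-t\,x'\hat\beta)}, independent of the baseline family.
#' Pointwise intervals are delta-method intervals on \eqn{t\,x'\beta}
#' mapped through \eqn{\exp(-\cdot)}.
#'
#' @param fit A converged [ah_fit()] object.
#' @param t Times at which to evaluate the curve.
#' @param x Covariate profile (default: a single covariate set to 1).
#' @param level Confidence level.
#' @return Data frame with columns `time`, `estimate`, `lower`, `upper`.
#' @export
relative_survival_curve <- function(fit, t, x = 1, level = fit$ci_level) {
  stopifnot(inherits(fit, "ah_fit"))
  .check_time(t)
  p <- length(fit$beta)
  x <- as.numeric(x)
  if (length(x) != p) stop("'x' must match length(beta)", call. = FALSE)
  k_theta <- length(fit$theta)
  Vb <- fit$vcov[k_theta + seq_len(p), k_theta + seq_len(p), drop = FALSE]
  xb <- sum(x * fit$beta)
  se_xb <- sqrt(drop(crossprod(x, Vb %*% x)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(time = t,
             estimate = exp(-t * xb),
             lower = exp(-t * (xb + z * se_xb)),
             upper = exp(-t * (xb - z * se_xb)))
}
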