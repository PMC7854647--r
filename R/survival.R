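# Disease-specific survival analyses: Kaplan-Meier product-limit curves with
# at-risk reporting, log-rank (Mantel-Cox) tests, and Cox proportional-
# hazards fits with Efron tie handling. Estimation is delegated to the
# survival package behind this module's surface; the test suite verifies the
# numbers against hand-written product-limit / hypergeometric / partial-
# likelihood computations.

#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimator over event times; censoring at a time equal to an
#' event time is handled after the events (standard convention). An
#' all-censored group yields S identically 1.
#'
#' @param time Follow-up in months (> 0).
#' @param event 1 = died of melanoma, 0 = censored (alive, or dead of
#'   another cause).
#' @param report_times Months at which the number at risk is reported
#'   (default 0 and 100).
#' @return Object of class `km_curve`: list with `table` (data.frame: time,
#'   n_risk, n_event, n_censor, surv over all distinct observed times),
#'   `at_risk` (data.frame: time, n_risk), `n`, `n_events`.
#' @export
km_estimate <- function(time, event, report_times = c(0, 100)) {
  check_surv(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  sm <- summary(fit, times = report_times, extend = TRUE)
  structure(list(table = tab,
                 at_risk = data.frame(time = sm$time, n_risk = sm$n.risk),
                 n = length(time), n_events = sum(event)),
            class = "km_curve")
}

#' Log-rank (Mantel-Cox) test
#'
#' Chi-square statistic (O - E)^2 / V with hypergeometric expectation and
#' variance summed over distinct event times; p from the chi-square
#' distribution with (groups - 1) df.
#'
#' @param time,event Survival outcome for all subjects pooled.
#' @param group Group membership (two or more levels).
#' @return Object of class `logrank_result`: list with `statistic`, `df`,
#'   `p_value`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    abort_validation("log-rank test needs at least two non-empty groups")
  if (sum(event) == 0) abort_validation("no events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  df <- length(sd$n) - 1
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 observed = sd$obs, expected = sd$exp),
            class = "logrank_result")
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Efron tie handling by default;
#' Breslow available for comparison with other software) over the named
#' covariate columns of `data`, using complete cases only. Covariate coding
#' conventions: the high-risk ADTA indicator is 1 for high risk, ulceration
#' 1 when present, Breslow depth continuous in mm, and T stage, TIL grade
#' and stage as ordinal numeric scores.
#'
#' @param data `data.frame` with columns `time`, `event`, and the covariates.
#' @param covariates Character vector of covariate column names (order is
#'   preserved in the output table).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `adta_cox`: list with `table` (data.frame: term,
#'   beta, se, hr, ci_low, ci_high, p_value, flagged), `loglik`,
#'   `score_statistic`, `n_used`, `n_events`, `ties`.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  miss <- setdiff(c("time", "event", covariates), names(data))
  if (length(miss))
    abort_format("data is missing column(s): %s", paste(miss, collapse = ", "))
  use <- stats::complete.cases(data[c("time", "event", covariates)])
  d <- data[use, , drop = FALSE]
  check_surv(d$time, d$event)
  if (sum(d$event) < 1)
    abort_validation("no events among complete cases")
  for (cc in covariates) {
    if (length(unique(d[[cc]])) < 2)
      abort_validation("covariate '%s' is constant on complete cases", cc)
  }
  qx <- qr(scale(as.matrix(d[covariates]), scale = FALSE))
  if (qx$rank < length(covariates))
    abort_validation("covariates are collinear on complete cases")
  fml <- stats::reformulate(covariates,
                            response = "survival::Surv(time, event)")
  fit_warnings <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties),
    warning = function(w) {
      fit_warnings <<- c(fit_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (!is.null(fit$fail))
    abort_validation("Cox fit failed: %s", paste(fit$fail, collapse = "; "))
  sm <- summary(fit)
  se <- sm$coefficients[, "se(coef)"]
  beta <- sm$coefficients[, "coef"]
  # complete separation shows up as a diverging coefficient / huge SE
  flagged <- !is.finite(beta) | !is.finite(se) | se > 50 | abs(beta) > 50
  tab <- data.frame(term = covariates, beta = unname(beta), se = unname(se),
                    hr = unname(exp(beta)),
                    ci_low = unname(exp(beta - 1.96 * se)),
                    ci_high = unname(exp(beta + 1.96 * se)),
                    p_value = unname(sm$coefficients[, "Pr(>|z|)"]),
                    flagged = unname(flagged))
  if (any(flagged)) {
    warning(sprintf("possible complete separation for: %s (unbounded CI)",
                    paste(covariates[flagged], collapse = ", ")))
  } else if (length(fit_warnings)) {
    warning(paste(unique(fit_warnings), collapse = "; "))
  }
  structure(list(table = tab, loglik = fit$loglik[2],
                 score_statistic = unname(sm$sctest["test"]),
                 n_used = sm$n, n_events = sm$nevent, ties = ties),
            class = "adta_cox")
}

check_surv <- function(time, event) {
  if (length(time) != length(event) || !length(time))
    abort_validation("time and event must be non-empty and equal length")
  if (anyNA(time) || any(time <= 0))
    abort_validation("all follow-up times must be positive")
  if (!all(event %in% c(0, 1)))
    abort_validation("event indicators must be 0/1")
  invisible(TRUE)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d\n", x$n, x$n_events))
  for (i in seq_len(nrow(x$at_risk)))
    cat(sprintf("  at risk at %g months: %d\n",
                x$at_risk$time[i], x$at_risk$n_risk[i]))
  invisible(x)
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square = %.4f (%d df), p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
print.adta_cox <- function(x, ...) {
  cat(sprintf("<adta_cox> n = %d, events = %d, ties = %s\n",
              x$n_used, x$n_events, x$ties))
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-12s HR = %6.2f (%.2f-%.2f), p = %.4g%s\n",
                tab$term[i], tab$hr[i], tab$ci_low[i], tab$ci_high[i],
                tab$p_value[i], if (tab$flagged[i]) "  [separation]" else ""))
  invisible(x)
}
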