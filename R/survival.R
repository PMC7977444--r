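#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator via `survival::survfit`, with the median as
#' the earliest time at which the estimated survival drops to 0.5 or
#' below and a 95% confidence interval for the median obtained by
#' intersecting the log-transformed Greenwood confidence band with 0.5
#' (the Brookmeyer-Crowley construction). A median (or CI bound) that
#' the data never reach is reported as `NA` ("not reached").
#'
#' @param time follow-up times in months (>= 0).
#' @param event logical or 0/1; `TRUE`/1 = death, `FALSE`/0 =
#'   right-censored (other-treatment start or last study visit).
#' @return An object of class `km_estimate`: `curve` (data frame `time`,
#'   `n_risk`, `n_event`, `surv`, `lower`, `upper`), `median`,
#'   `median_ci` (length 2, `NA` = not reached), `n`, `n_events`, and
#'   the underlying `survfit` object as `fit`.
#' @export
km_fit <- function(time, event) {
  time <- as.numeric(time)
  event <- as.integer(as.logical(event))
  if (length(time) < 1L) stop("need at least one record")
  if (any(!is.finite(time)) || any(time < 0))
    stop("survival times must be finite and non-negative")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log", conf.int = 0.95)
  q <- stats::quantile(fit, probs = 0.5)
  med <- unname(q$quantile)
  ci <- c(unname(q$lower), unname(q$upper))
  structure(list(
    curve = data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv,
                       lower = fit$lower, upper = fit$upper),
    median = med, median_ci = ci,
    n = length(time), n_events = sum(event), fit = fit
  ), class = "km_estimate")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km a `km_estimate`.
#' @param t times at which to evaluate the (right-continuous) step
#'   function; `S(0) = 1` before the first event.
#' @return Numeric vector of survival probabilities.
#' @export
km_surv <- function(km, t) {
  stopifnot(inherits(km, "km_estimate"))
  vapply(t, function(tt) {
    i <- which(km$curve$time <= tt)
    if (length(i) == 0L) 1 else km$curve$surv[max(i)]
  }, numeric(1))
}

#' @export
print.km_estimate <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached" else signif(x$median, 4)
  ci <- ifelse(is.na(x$median_ci), "NR", signif(x$median_ci, 4))
  cat("<km_estimate> n = ", x$n, ", events = ", x$n_events,
      ", median = ", med, " (95% CI ", ci[1], "-", ci[2], ")\n", sep = "")
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (O - E)^2 / V log-rank with hypergeometric variance, via
#' `survival::survdiff`; two-sided p from the chi-square distribution
#' with 1 degree of freedom. With zero observed events the statistic is
#' undefined and reported as `NA`.
#'
#' @param time,event as in [km_fit()].
#' @param group two-level grouping vector (e.g. "PR" vs "SD_or_PD").
#' @return List of class `logrank_result`: `chisq`, `p`, `n`,
#'   `n_events`, `groups`.
#' @export
logrank_test <- function(time, event, group) {
  time <- as.numeric(time)
  event <- as.integer(as.logical(event))
  group <- factor(group)
  if (nlevels(group) != 2L) stop("log-rank test needs exactly two groups")
  if (any(table(group) == 0L)) stop("both groups must be non-empty")
  if (sum(event) == 0L) {
    return(structure(list(chisq = NA_real_, p = NA_real_, n = length(time),
                          n_events = 0L, groups = levels(group),
                          note = "undefined: no events observed"),
                     class = "logrank_result"))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  structure(list(chisq = chisq,
                 p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 n = length(time), n_events = sum(event),
                 groups = levels(group)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("<logrank> chisq = ", signif(x$chisq, 4), ", p = ",
      signif(x$p, 3), " (", paste(x$groups, collapse = " vs "), ")\n",
      sep = "")
  invisible(x)
}

#' Survival stratification by response group
#'
#' Fits per-group Kaplan-Meier curves for responders (PR) versus
#' non-responders (SD or PD) and compares them by log-rank — the
#' standard outcome analysis for a response-assessment method.
#'
#' @param records data frame with columns `time_months`, `event` (0/1)
#'   and `group` (two levels, e.g. "PR" and "SD_or_PD").
#' @return List of class `survival_stratification`: `by_group` (named
#'   list of `km_estimate`s), `logrank` (a `logrank_result`).
#' @export
stratify_survival <- function(records) {
  need <- c("time_months", "event", "group")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("survival table is missing columns: ",
         paste(missing, collapse = ", "))
  g <- factor(records$group)
  by_group <- lapply(levels(g), function(lv) {
    sel <- g == lv
    km_fit(records$time_months[sel], records$event[sel])
  })
  names(by_group) <- levels(g)
  lr <- if (nlevels(g) == 2L)
    logrank_test(records$time_months, records$event, g) else NULL
  structure(list(by_group = by_group, logrank = lr),
            class = "survival_stratification")
}

#' Export Kaplan-Meier curve points as CSV rows
#'
#' @param km a `km_estimate`.
#' @param group optional group label column.
#' @return Data frame `t`, `S`, `n_at_risk` (plus `group`).
#' @export
km_curve_table <- function(km, group = NULL) {
  stopifnot(inherits(km, "km_estimate"))
  out <- data.frame(t = km$curve$time, S = km$curve$surv,
                    n_at_risk = km$curve$n_risk)
  if (!is.null(group)) out <- cbind(group = group, out)
  out
}
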