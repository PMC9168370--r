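#' Kaplan-Meier product-limit curve
#'
#' @param times positive event/censoring times.
#' @param events 1 = event, 0 = censored.
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv` (step
#'   function values at the observed event times; `surv` starts at 1 and is
#'   non-increasing).
#' @export
km_curve <- function(times, events) {
  stop_if_not(length(times) > 0, "km_curve: empty input")
  stop_if_not(all(times > 0), "survival times must be positive")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' @param times positive survival times.
#' @param events 1 = event, 0 = censored.
#' @param group binary group indicator.
#' @return list with `chi2` (1 df) and two-sided `p`.
#' @export
logrank_test <- function(times, events, group) {
  stop_if_not(length(unique(group)) == 2, "need two nonempty groups")
  stop_if_not(sum(events) > 0, "log-rank needs at least one event")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ group)
  list(chi2 = unname(sd_$chisq),
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards model
#'
#' Maximum partial likelihood with Breslow tie handling; Wald confidence
#' interval and p-value for the binary group effect.
#'
#' @param times positive survival times.
#' @param events 1 = event, 0 = censored.
#' @param group binary covariate (the risk group).
#' @return list of class `cox_result`: `hr`, `ci` (low, high), `p`,
#'   `n_events`, `coef`, `se`.
#' @export
cox_univariate <- function(times, events, group) {
  stop_if_not(length(unique(group)) == 2,
              "group has no contrast (coded identically for all subjects)")
  stop_if_not(sum(events[group == unique(group)[1]]) >= 1 &&
              sum(events[group == unique(group)[2]]) >= 1,
              "each group needs at least one event")
  fit <- survival::coxph(survival::Surv(times, events) ~ group,
                         ties = "breslow",
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 50))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15)
    stop("monotone partial likelihood: the groups separate the risk sets",
         call. = FALSE)
  z <- beta / se
  structure(list(hr = exp(beta),
                 ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p = 2 * stats::pnorm(-abs(z)),
                 n_events = sum(events), coef = beta, se = se),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox: HR %.2f (95%% CI %.2f-%.2f), p = %.4g, %d events\n",
              x$hr, x$ci[1], x$ci[2], x$p, x$n_events))
  invisible(x)
}

#' Survival follow-through for a benchmark model
#'
#' Stratifies subjects by the model's out-of-fold predicted label (the
#' leakage-free choice of risk group), then runs Kaplan-Meier curves per
#' group, the log-rank test and a univariate Cox model.  Subjects without
#' survival data are dropped.
#'
#' @param record a `benchmark_record` (with out-of-fold predictions).
#' @param clinical data.frame with `os_time`, `os_event` (order matching the
#'   benchmark's subjects).
#' @return list with `km` (per-group curves), `logrank`, `cox`, `groups`.
#' @export
survival_analysis <- function(record, clinical) {
  grp <- record$oof_label
  keep <- !is.na(grp) & is.finite(clinical$os_time) &
    !is.na(clinical$os_event)
  tt <- clinical$os_time[keep]; ev <- clinical$os_event[keep]
  gg <- grp[keep]
  km <- lapply(split(seq_along(tt), gg),
               function(i) km_curve(tt[i], ev[i]))
  # risk group = predicted progression, so HR > 1 means the model's
  # progression group dies faster
  risk <- as.integer(gg == 0)
  list(km = km,
       logrank = logrank_test(tt, ev, gg),
       cox = cox_univariate(tt, ev, risk),
       groups = gg, n = sum(keep))
}
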