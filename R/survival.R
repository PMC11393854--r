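#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survivor function under right censoring.
#' The median is the earliest time at which the estimated survival drops
#' to 0.5 or below, and is undefined (`NA`) when the curve never reaches
#' 0.5.
#'
#' @param times Non-negative event/censoring times.
#' @param events Logical (or 0/1) event indicators, same length.
#' @return Object of class `km_curve`: data.frame `curve` with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`, plus `median` and
#'   `n`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) validation_error("empty survival input")
  if (length(times) != length(events))
    validation_error("times and events must have the same length")
  if (any(is.na(times)) || any(times < 0))
    validation_error("times must be non-negative and non-missing")
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  med <- if (any(curve$surv <= 0.5)) min(curve$time[curve$surv <= 0.5]) else NA_real_
  structure(list(curve = curve, median = med, n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, median survival = %s\n", x$n,
              ifelse(is.na(x$median), "not reached", format(x$median))))
  print(head(x$curve, 10))
  if (nrow(x$curve) > 10) cat("  ...\n")
  invisible(x)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected chi-squared statistic with k-1 degrees
#' of freedom.
#'
#' @param times,events As in [km_estimate()].
#' @param group Group labels (>= 2 non-empty groups, >= 1 event overall).
#' @return list with `chisq`, `df` and `p`.
#' @export
logrank <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) < 2) validation_error("need >= 2 groups")
  if (any(table(group) == 0)) validation_error("every group must be non-empty")
  if (!any(as.logical(events))) validation_error("need >= 1 event overall")
  sd <- survival::survdiff(survival::Surv(times, as.logical(events)) ~ group)
  df <- nlevels(group) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards contrast between two groups
#'
#' Partial-likelihood hazard-ratio estimate with Efron handling of tied
#' event times (serial monitoring at months resolution guarantees ties)
#' and a Wald 95% confidence interval; the log-rank test is reported
#' alongside. When one group has no events the partial likelihood is
#' monotone: the fit is flagged `monotone = TRUE` and the confidence
#' interval is unbounded on one side rather than an error.
#'
#' @param times,events As in [km_estimate()].
#' @param group Binary group labels; the hazard ratio is for the second
#'   level relative to the first (factor level order).
#' @return Object of class `hazard_estimate`: `hr`, `ci_lower`, `ci_upper`,
#'   `wald_p`, `logrank_chisq`, `logrank_p`, `n` and `events` per group,
#'   and the `monotone` flag.
#' @export
cox_hr <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) != 2)
    validation_error("cox_hr compares exactly two groups")
  if (any(table(group) == 0)) validation_error("both groups must be non-empty")
  events <- as.logical(events)
  if (!any(events)) validation_error("need >= 1 event")
  ev_by_group <- tapply(events, group, sum)
  monotone <- any(ev_by_group == 0)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(times, events) ~ group, ties = "efron"))
  beta <- unname(coef(fit))
  se <- sqrt(unname(vcov(fit)[1, 1]))
  ci <- exp(beta + c(-1, 1) * 1.96 * se)
  if (monotone) ci <- if (beta > 0) c(exp(beta - 1.96 * se), Inf) else c(0, exp(beta + 1.96 * se))
  lr <- logrank(times, events, group)
  structure(list(hr = exp(beta), ci_lower = ci[1], ci_upper = ci[2],
                 wald_p = 2 * stats::pnorm(-abs(beta / se)),
                 logrank_chisq = lr$chisq, logrank_p = lr$p,
                 n = table(group), events = ev_by_group,
                 monotone = monotone),
            class = "hazard_estimate")
}

#' @export
print.hazard_estimate <- function(x, ...) {
  cat(sprintf("HR = %.3f (95%% CI %.3f-%.3f), log-rank p = %.4g%s\n",
              x$hr, x$ci_lower, x$ci_upper, x$logrank_p,
              if (x$monotone) " [monotone likelihood: a group has no events]" else ""))
  cat(sprintf("  n = %s, events = %s\n",
              paste(x$n, collapse = "/"), paste(x$events, collapse = "/")))
  invisible(x)
}

#' Survival contrast between coMMstant groups of a cohort
#'
#' Convenience wrapper: joins a coMMstant classification onto the patient
#' table and contrasts PFS or OS between index 0 (reference) and index 1.
#'
#' @param cohort A [cmmc_cohort()].
#' @param commstant data.frame from [classify_cohort_commstant()].
#' @param endpoint `"pfs"` or `"os"`.
#' @return list with per-group [km_estimate()] curves and the
#'   [cox_hr()] estimate (index 1 vs index 0).
#' @export
survival_by_commstant <- function(cohort, commstant, endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  pat <- merge(cohort$patients, commstant, by = "patient_id")
  pat <- pat[pat$index %in% c("0", "1"), , drop = FALSE]
  tcol <- paste0(endpoint, "_months"); ecol <- paste0(endpoint, "_event")
  pat <- pat[!is.na(pat[[tcol]]) & !is.na(pat[[ecol]]), , drop = FALSE]
  if (!nrow(pat)) validation_error("no classified patients with survival data")
  grp <- factor(pat$index, levels = c("0", "1"))
  list(endpoint = endpoint,
       curves = lapply(split(pat, grp), function(d)
         km_estimate(d[[tcol]], d[[ecol]])),
       cox = cox_hr(pat[[tcol]], pat[[ecol]], grp))
}
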