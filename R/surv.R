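# Kaplan-Meier estimation, log-rank comparison, reverse-KM follow-up,
# and relapse-free-survival endpoint derivation

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator (via [survival::survfit()], events before
#' censorings at tied times). The median is the first time at which the
#' survival step function falls to 0.5 or below, undefined (`NA`) when the
#' curve never does.
#'
#' @param time nonnegative follow-up times in months.
#' @param event logical or 0/1 event indicators (TRUE = failure).
#' @return An object of class `km_curve`: data frame `$curve` with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`, `std_err` (Greenwood),
#'   plus `$median` and `$n`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) > 0, all(time >= 0))
  event <- as.numeric(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "log-log")
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv, std_err = fit$std.err * fit$surv)
  med <- if (any(curve$surv <= 0.5)) min(curve$time[curve$surv <= 0.5]) else NA_real_
  structure(list(curve = curve, median = med, n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", median =",
      if (is.na(x$median)) "not reached" else paste(x$median, "months"), "\n")
  invisible(x)
}

#' Survival rate at a fixed horizon
#'
#' Reads the step function just before `t` (the `S(t-)` convention at exact
#' event times). Typical horizons: 24 months (2-year rate) and 60 months
#' (5-year rate).
#'
#' @param curve a [km_estimate()] result.
#' @param t horizon in months.
#' @return Survival probability.
#' @export
km_rate <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  before <- curve$curve$time < t
  if (!any(before)) return(1)
  curve$curve$surv[max(which(before))]
}

#' Export a survival curve as TSV
#'
#' @param curve a [km_estimate()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  utils::write.table(curve$curve, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Relapse-free survival endpoints
#'
#' RFS is measured from the date of documented complete remission (CR);
#' failures are relapse and death in CR, censoring is alive in CR at last
#' follow-up. Patients without CR are excluded. Times are derived as
#' `rfs_time - cr_time` (both in months from diagnosis).
#'
#' @param cohort cohort data frame.
#' @return Data frame with `patient_id`, `time`, `event`, `exposure_group` for
#'   patients with CR; an error if a CR patient with RFS data lacks `cr_time`.
#' @export
rfs_endpoints <- function(cohort) {
  cr <- which(!is.na(cohort$cr_achieved) & cohort$cr_achieved)
  if (length(cr) == 0)
    return(data.frame(patient_id = character(0), time = numeric(0),
                      event = logical(0), exposure_group = character(0)))
  sub <- cohort[cr, , drop = FALSE]
  has_rfs <- !is.na(sub$rfs_time)
  if (any(has_rfs & is.na(sub$cr_time)))
    stop("cr_time missing despite cr_achieved for patient(s): ",
         paste(sub$patient_id[has_rfs & is.na(sub$cr_time)], collapse = ", "))
  sub <- sub[has_rfs, , drop = FALSE]
  time <- sub$rfs_time - sub$cr_time
  if (any(time < 0))
    stop("rfs_time before cr_time for patient(s): ",
         paste(sub$patient_id[time < 0], collapse = ", "))
  data.frame(patient_id = sub$patient_id, time = time,
             event = as.logical(sub$rfs_event),
             exposure_group = sub$exposure_group,
             stringsAsFactors = FALSE)
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square across two or more
#' groups (via [survival::survdiff()]), `df = groups - 1`. With no events in
#' any group the statistic is 0 and p = 1.
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param group group labels (at least two nonempty groups).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stop("need at least two nonempty groups")
  df <- nlevels(group) - 1
  if (sum(as.numeric(event)) == 0)
    return(list(statistic = 0, df = df, p_value = 1))
  sd <- survival::survdiff(survival::Surv(time, as.numeric(event)) ~ group)
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Kaplan-Meier with the event indicator flipped, so censorings become the
#' "events": the median of that curve estimates the median follow-up time.
#' Undefined (`NA`) when every patient died (no censoring-time distribution).
#'
#' @param time follow-up times.
#' @param event event indicators (TRUE = death/failure).
#' @return Median follow-up in months, or `NA`.
#' @export
reverse_km_followup <- function(time, event) {
  km_estimate(time, !as.logical(event))$median
}
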