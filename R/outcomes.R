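# LVEF outcome comparison at discrete timepoints, weighted (IPW
# pseudo-population) and unweighted, plus within-group change from baseline

#' Weighted mean and standard deviation
#'
#' Mean `sum(w x) / sum(w)` and the frequency-weight standard deviation
#' `sqrt(sum(w (x - m)^2) / (sum(w) - 1))`; with unit weights these are the
#' ordinary mean and sample SD.
#'
#' @param values numeric values.
#' @param weights nonnegative weights; at least two must be positive and their
#'   sum must exceed 1 for the variance to be defined.
#' @return List with `mean`, `sd`, `sum_w`.
#' @export
weighted_mean_sd <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  keep <- weights > 0
  values <- values[keep]; weights <- weights[keep]
  if (length(values) < 2) stop("need at least two observations with positive weight")
  if (sum(weights) <= 1) stop("sum of weights must exceed 1 (variance undefined)")
  m <- wtd_mean(values, weights)
  list(mean = m, sd = sqrt(wtd_var(values, weights)), sum_w = sum(weights))
}

#' Unpaired two-sample t-test, optionally weighted
#'
#' Compares two (weighted) samples of LVEF values. The default Welch variant
#' uses `SE = sqrt(v1/n1 + v0/n0)` with the weighted group sizes `n_g` and the
#' Welch-Satterthwaite degrees of freedom; `variant = "pooled"` gives the
#' classical equal-variance test. Two weight conventions are available:
#' `"frequency"` takes `n_g = sum(w)` at face value, as frequency-weighting
#' statistical software does; `"ess"` rescales each group's weights so that
#' they sum to the Kish effective sample size, which protects the test from
#' treating a heavily reweighted patient as many independent ones. With unit
#' weights the two conventions coincide.
#'
#' @param x1,x0 numeric samples (group 1 minus group 0 is reported).
#' @param w1,w0 optional nonnegative weights.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param convention `"frequency"` (default) or `"ess"`.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return List with `mean_difference`, `ci95` (length-2 vector), `p_value`,
#'   `t`, `df`, `n1`, `n0`.
#' @export
unpaired_ttest <- function(x1, x0, w1 = NULL, w0 = NULL,
                           variant = c("welch", "pooled"),
                           convention = c("frequency", "ess"),
                           conf_level = 0.95) {
  variant <- match.arg(variant)
  convention <- match.arg(convention)
  w1 <- w1 %||% rep(1, length(x1))
  w0 <- w0 %||% rep(1, length(x0))
  k1 <- w1 > 0; x1 <- x1[k1]; w1 <- w1[k1]
  k0 <- w0 > 0; x0 <- x0[k0]; w0 <- w0[k0]
  if (length(x1) < 2 || length(x0) < 2)
    stop("need at least 2 effective observations per group")
  if (convention == "ess") {
    w1 <- w1 * kish_ess(w1) / sum(w1)
    w0 <- w0 * kish_ess(w0) / sum(w0)
  }
  n1 <- sum(w1); n0 <- sum(w0)
  m1 <- wtd_mean(x1, w1); m0 <- wtd_mean(x0, w0)
  v1 <- wtd_var(x1, w1); v0 <- wtd_var(x0, w0)
  diff <- m1 - m0
  if (variant == "welch") {
    se2 <- v1 / n1 + v0 / n0
    se <- sqrt(se2)
    df <- if (se2 > 0)
      se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)) else NA_real_
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- n1 + n0 - 2
  }
  if (!is.finite(se) || se == 0) {
    # both groups degenerate: equal means -> p = 1 with a zero-width interval
    p <- if (diff == 0) 1 else 0
    return(list(mean_difference = diff, ci95 = c(diff, diff), p_value = p,
                t = if (diff == 0) 0 else Inf, df = df, n1 = n1, n0 = n0))
  }
  tval <- diff / se
  p <- 2 * stats::pt(-abs(tval), df)
  half <- stats::qt(1 - (1 - conf_level) / 2, df) * se
  list(mean_difference = diff, ci95 = c(diff - half, diff + half),
       p_value = p, t = tval, df = df, n1 = n1, n0 = n0)
}

.sig_tier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

# weights for a timepoint analysis: named vector keyed by patient_id
.wc_weights <- function(wc) {
  w <- wc$weight
  names(w) <- wc$patient_id
  w
}

#' Exposed-vs-control LVEF effect at each timepoint
#'
#' For each timepoint window, compares the exposed and control LVEF samples
#' with an unpaired t-test and reports the mean difference (exposed minus
#' control), its confidence interval, p-value and significance tier (`*`,
#' `**`, `***` at 0.05 / 0.01 / 0.001). When a weighted cohort is supplied,
#' only untrimmed patients contribute, each with their final inverse
#' probability weight (the IPW pseudo-population estimate of the average
#' treatment effect); otherwise all patients of the model's comparison groups
#' contribute with unit weight. A timepoint with fewer than two contributing
#' patients in either group is flagged non-estimable rather than raising.
#'
#' @param cohort cohort data frame.
#' @param model `"model1"` or `"model2"`; ignored when `wc` is given (the
#'   weighted cohort already encodes the comparison).
#' @param windows a [timepoint_windows()] object.
#' @param wc optional `weighted_cohort`.
#' @param rule echo-to-window assignment rule, see [assign_timepoints()].
#' @param variant,convention passed to [unpaired_ttest()].
#' @return Data frame with one row per timepoint: group means/SDs, group sizes
#'   (sums of weights), `mean_difference`, `ci_low`, `ci_high`, `p_value`,
#'   `significance`, `weighted`, `estimable`.
#' @export
timepoint_effects <- function(cohort, model = c("model2", "model1"),
                              windows = default_windows(), wc = NULL,
                              rule = "closest_to_window_center",
                              variant = "welch", convention = "frequency") {
  model <- match.arg(model)
  if (is.null(wc)) {
    ms <- model_subset(cohort, model)
    sub <- ms$cohort; exposed <- ms$exposed
    w <- rep(1, nrow(sub))
  } else {
    idx <- match(wc$patient_id, cohort$patient_id)
    sub <- cohort[idx, , drop = FALSE]
    exposed <- wc$exposed
    w <- wc$weight
  }
  tm <- timepoint_matrix(sub, windows, rule)
  out <- NULL
  for (tp in names(windows)) {
    lv <- tm[[tp]]
    ok <- !is.na(lv) & w > 0
    x1 <- lv[ok & exposed]; w1 <- w[ok & exposed]
    x0 <- lv[ok & !exposed]; w0 <- w[ok & !exposed]
    if (length(x1) < 2 || length(x0) < 2) {
      row <- data.frame(timepoint = tp, n_exposed = length(x1),
                        n_control = length(x0),
                        sum_w_exposed = sum(w1), sum_w_control = sum(w0),
                        mean_exposed = NA_real_, sd_exposed = NA_real_,
                        mean_control = NA_real_, sd_control = NA_real_,
                        mean_difference = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        significance = NA_character_,
                        weighted = !is.null(wc), estimable = FALSE,
                        stringsAsFactors = FALSE)
    } else {
      s1 <- weighted_mean_sd(x1, w1)
      s0 <- weighted_mean_sd(x0, w0)
      tt <- unpaired_ttest(x1, x0, w1, w0, variant = variant,
                           convention = convention)
      row <- data.frame(timepoint = tp, n_exposed = length(x1),
                        n_control = length(x0),
                        sum_w_exposed = s1$sum_w, sum_w_control = s0$sum_w,
                        mean_exposed = s1$mean, sd_exposed = s1$sd,
                        mean_control = s0$mean, sd_control = s0$sd,
                        mean_difference = tt$mean_difference,
                        ci_low = tt$ci95[1], ci_high = tt$ci95[2],
                        p_value = tt$p_value,
                        significance = .sig_tier(tt$p_value),
                        weighted = !is.null(wc), estimable = TRUE,
                        stringsAsFactors = FALSE)
    }
    out <- rbind(out, row)
  }
  out
}

#' Within-group LVEF change from baseline
#'
#' For one group (exposed or control), compares the LVEF sample at each
#' post-therapy timepoint `t1`-`t3` against the group's pre-therapy `t0`
#' sample with an unpaired t-test (the echo subsets differ across timepoints,
#' so the panels are unbalanced and a paired test is not generally possible).
#'
#' @inheritParams timepoint_effects
#' @param group `"exposed"` or `"control"`.
#' @param paired if `TRUE`, restrict to patients measured at both timepoints
#'   and test the paired differences (sensitivity analysis; unit weights only).
#' @return Data frame with `group`, `timepoint`, `mean_change_vs_t0`,
#'   `p_value`, `estimable`.
#' @export
within_group_change <- function(cohort, model = c("model2", "model1"),
                                group = c("exposed", "control"),
                                windows = default_windows(), wc = NULL,
                                rule = "closest_to_window_center",
                                variant = "welch", convention = "frequency",
                                paired = FALSE) {
  model <- match.arg(model)
  group <- match.arg(group)
  if (is.null(wc)) {
    ms <- model_subset(cohort, model)
    sub <- ms$cohort; exposed <- ms$exposed
    w <- rep(1, nrow(sub))
  } else {
    idx <- match(wc$patient_id, cohort$patient_id)
    sub <- cohort[idx, , drop = FALSE]
    exposed <- wc$exposed
    w <- wc$weight
  }
  in_group <- if (group == "exposed") exposed else !exposed
  tm <- timepoint_matrix(sub, windows, rule)
  out <- NULL
  for (tp in setdiff(names(windows), "t0")) {
    if (paired) {
      ok <- in_group & !is.na(tm[[tp]]) & !is.na(tm$t0) & w > 0
      d <- tm[[tp]][ok] - tm$t0[ok]
      if (length(d) < 2) {
        row <- data.frame(group = group, timepoint = tp,
                          mean_change_vs_t0 = NA_real_, p_value = NA_real_,
                          estimable = FALSE, stringsAsFactors = FALSE)
      } else {
        tt <- stats::t.test(d)
        row <- data.frame(group = group, timepoint = tp,
                          mean_change_vs_t0 = mean(d),
                          p_value = tt$p.value, estimable = TRUE,
                          stringsAsFactors = FALSE)
      }
    } else {
      ok_k <- in_group & !is.na(tm[[tp]]) & w > 0
      ok_0 <- in_group & !is.na(tm$t0) & w > 0
      xk <- tm[[tp]][ok_k]; wk <- w[ok_k]
      x0 <- tm$t0[ok_0]; w0 <- w[ok_0]
      if (length(xk) < 2 || length(x0) < 2) {
        row <- data.frame(group = group, timepoint = tp,
                          mean_change_vs_t0 = NA_real_, p_value = NA_real_,
                          estimable = FALSE, stringsAsFactors = FALSE)
      } else {
        tt <- unpaired_ttest(xk, x0, wk, w0, variant = variant,
                             convention = convention)
        row <- data.frame(group = group, timepoint = tp,
                          mean_change_vs_t0 = tt$mean_difference,
                          p_value = tt$p_value, estimable = TRUE,
                          stringsAsFactors = FALSE)
      }
    }
    out <- rbind(out, row)
  }
  out
}
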