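# covariate balance diagnostics: absolute standardized mean differences,
# before and after weighting, with Kish effective sample sizes

#' Standardized mean difference for a continuous covariate
#'
#' `|m1 - m0| / sqrt((s1^2 + s0^2) / 2)`: the absolute difference of the
#' (optionally weighted) group means divided by the pooled standard deviation.
#' It measures the effect size between two groups and does not depend on the
#' sample sizes. Weighted moments follow the frequency-weight convention
#' (`sum(w (x - m)^2) / (sum(w) - 1)`).
#'
#' @param x_exposed,x_control numeric values in each group.
#' @param w_exposed,w_control optional nonnegative weights (default: all 1).
#' @return Nonnegative number; 0 when both pooled variance and mean difference
#'   are 0, an error when the pooled variance is 0 but the means differ.
#' @export
smd_continuous <- function(x_exposed, x_control,
                           w_exposed = NULL, w_control = NULL) {
  w1 <- w_exposed %||% rep(1, length(x_exposed))
  w0 <- w_control %||% rep(1, length(x_control))
  keep1 <- w1 > 0; keep0 <- w0 > 0
  x1 <- x_exposed[keep1]; w1 <- w1[keep1]
  x0 <- x_control[keep0]; w0 <- w0[keep0]
  if (length(x1) < 2 || length(x0) < 2)
    stop("need at least 2 effective observations per group")
  m1 <- wtd_mean(x1, w1); m0 <- wtd_mean(x0, w0)
  v1 <- wtd_var(x1, w1); v0 <- wtd_var(x0, w0)
  pooled <- sqrt((v1 + v0) / 2)
  if (pooled == 0) {
    if (m1 == m0) return(0)
    stop("zero pooled standard deviation with unequal means")
  }
  abs(m1 - m0) / pooled
}

#' Standardized difference for a binary covariate
#'
#' `|p1 - p0| / sqrt((p1 (1 - p1) + p0 (1 - p0)) / 2)` on the two group
#' proportions. When both proportions are 0 or both are 1 the difference is 0;
#' when the denominator vanishes but the proportions differ (one group all
#' positive, the other all negative) the result is `Inf` with a warning, so
#' separation-like pathologies surface instead of being dropped.
#'
#' @param p_exposed,p_control proportions in `[0, 1]`.
#' @return Nonnegative number (possibly `Inf`).
#' @export
smd_binary <- function(p_exposed, p_control) {
  stopifnot(p_exposed >= 0, p_exposed <= 1, p_control >= 0, p_control <= 1)
  num <- abs(p_exposed - p_control)
  den <- sqrt((p_exposed * (1 - p_exposed) + p_control * (1 - p_control)) / 2)
  if (den == 0) {
    if (num == 0) return(0)
    warning("degenerate binary covariate (0/1 split between groups); SMD is Inf")
    return(Inf)
  }
  num / den
}

#' Covariate balance report
#'
#' One row per continuous covariate and per non-reference level of each
#' categorical covariate, giving the absolute standardized difference between
#' exposed and control groups before weighting (all patients in the weighted
#' cohort, unit weights, trimmed patients included) and after weighting
#' (untrimmed patients with their final weights). A covariate counts as
#' balanced when the weighted SMD is at or below `threshold` (default 0.1).
#'
#' @param cohort cohort data frame.
#' @param wc a `weighted_cohort` (see [compute_weights()]).
#' @param covariates covariate names; see [default_ps_covariates()].
#' @param threshold balance threshold on the weighted SMD.
#' @return A `balance_report` data frame with columns `covariate`,
#'   `smd_unweighted`, `smd_weighted`, `balanced`, and attributes `threshold`,
#'   `ess_exposed`, `ess_control` (Kish effective sizes of the weighted
#'   groups).
#' @export
balance_report <- function(cohort, wc, covariates = default_ps_covariates(),
                           threshold = 0.1) {
  stopifnot(inherits(wc, "weighted_cohort"))
  idx <- match(wc$patient_id, cohort$patient_id)
  if (any(is.na(idx))) stop("weighted cohort contains patients absent from the cohort")
  sub <- cohort[idx, , drop = FALSE]
  des <- ps_design(sub, covariates)
  X <- des$X
  if (any(is.na(X)))
    stop("missing covariate values among weighted patients; fit the propensity ",
         "model on the same covariate set first")

  e <- wc$exposed
  w_unw <- rep(1, nrow(wc))
  w_wtd <- wc$weight          # 0 for trimmed patients

  one_smd <- function(col, w) {
    x1 <- X[e, col]; x0 <- X[!e, col]
    w1 <- w[e]; w0 <- w[!e]
    if (all(X[, col] %in% c(0, 1))) {
      p1 <- wtd_mean(x1[w1 > 0], w1[w1 > 0])
      p0 <- wtd_mean(x0[w0 > 0], w0[w0 > 0])
      smd_binary(p1, p0)
    } else {
      smd_continuous(x1, x0, w1, w0)
    }
  }

  rows <- data.frame(
    covariate = colnames(X),
    smd_unweighted = vapply(colnames(X), one_smd, numeric(1), w = w_unw),
    smd_weighted = vapply(colnames(X), one_smd, numeric(1), w = w_wtd),
    stringsAsFactors = FALSE, row.names = NULL
  )
  rows$balanced <- rows$smd_weighted <= threshold
  structure(rows,
            threshold = threshold,
            ess_exposed = kish_ess(w_wtd[e]),
            ess_control = kish_ess(w_wtd[!e]),
            class = c("balance_report", "data.frame"))
}

#' Love-plot data
#'
#' The balance report ordered by unweighted SMD, descending: the row order of
#' the classical Love plot.
#'
#' @param report a [balance_report()] result.
#' @return The reordered data frame.
#' @export
love_plot_data <- function(report) {
  stopifnot(inherits(report, "balance_report"))
  report[order(-report$smd_unweighted), , drop = FALSE]
}

#' Write balance diagnostics as TSV
#'
#' @param report a [balance_report()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_balance <- function(report, path) {
  utils::write.table(love_plot_data(report), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
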