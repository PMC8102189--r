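# fixtures are built in code: small deterministic cohorts for unit tests

# minimal valid cohort with given exposure groups and optional overrides
make_cohort <- function(exposure_group, ..., echo = NULL) {
  n <- length(exposure_group)
  cohort <- data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    exposure_group = exposure_group,
    age = rep(50, n),
    sex = rep("male", n),
    aml_history = rep("de_novo", n),
    wbc = NA_real_, platelets = NA_real_, hemoglobin = NA_real_,
    cytogenetic_risk = rep("intermediate", n),
    cad = rep(FALSE, n), valvular_disease = rep(FALSE, n),
    heart_failure = rep(FALSE, n), cv_risk_factor_count = rep(0, n),
    acei_arb = rep(FALSE, n), beta_blocker = rep(FALSE, n), mra = rep(FALSE, n),
    anthracycline_dose = rep(240, n),
    intensive_induction = rep(TRUE, n), cr_achieved = rep(FALSE, n),
    os_time = rep(12, n), os_event = rep(FALSE, n),
    cr_time = NA_real_, rfs_time = NA_real_, rfs_event = NA,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) cohort[[nm]] <- over[[nm]]
  if (is.null(echo)) {
    cohort$echo_months <- replicate(n, numeric(0), simplify = FALSE)
    cohort$echo_lvef <- replicate(n, numeric(0), simplify = FALSE)
  } else {
    cohort$echo_months <- lapply(echo, `[[`, "months")
    cohort$echo_lvef <- lapply(echo, `[[`, "lvef")
  }
  class(cohort) <- c("aml_cohort", "data.frame")
  cohort
}

# cohort reproducing a 2x2 covariate-by-exposure table:
# exposed n1 with x1 positives, control n0 with x0 positives, on covariate `cad`
make_2x2_cohort <- function(n1, x1, n0, x0) {
  grp <- c(rep("IDH2", n1), rep("WT", n0))
  cad <- c(rep(TRUE, x1), rep(FALSE, n1 - x1), rep(TRUE, x0), rep(FALSE, n0 - x0))
  make_cohort(grp, cad = cad)
}

# independent brute-force Pearson chi-square oracle
chi2_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# independent product-limit oracle: survival after each distinct time,
# events before censorings at ties
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  list(time = ts, surv = out)
}

# independent two-group log-rank oracle (hypergeometric moments)
logrank_oracle <- function(time, event, g1) {
  ts <- sort(unique(time[event == 1]))
  oe <- 0; v <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oe^2 / v
}
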