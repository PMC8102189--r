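# synthetic confounded AML cohort generator: covariate distributions echoing
# the study population, logistic exposure assignment, exposure-modified LVEF
# trajectories on an unbalanced echo panel, and exponential survival

#' Simulation configuration
#'
#' Defaults encode the study conditions the analysis targets: 363 patients
#' with an IDH1/2 mutation prevalence of 17.9% (IDH1:IDH2 split 26:39), median
#' age 60 with ~58% male patients, cardiovascular comorbidity more prevalent
#' among exposed patients via the logistic assignment model, a pre-therapy
#' LVEF around 58.5%, a control-arm decline of 3.1 points by the late
#' timepoint t3 (about 10 months after diagnosis) and an extra 13.5-point
#' decline attributable to exposure (58.5 to 55.4 vs 58.5 to 41.9), echoes
#' available for only a subset of patients per timepoint, and exponential
#' survival/censoring.
#'
#' @param n_patients cohort size.
#' @param seed integer seed; one seed drives one reproducible cohort.
#' @param exposure_prevalence target marginal probability of carrying an
#'   IDH1/2 mutation; the assignment intercept is calibrated to it.
#' @param idh1_fraction fraction of exposed patients carrying IDH1 (vs IDH2).
#' @param assignment_coefficients named log-odds on the assignment model
#'   covariates (`age_std` is `(age - 60) / 14`).
#' @param lvef_t0_mean,lvef_between_sd pre-therapy LVEF mean and
#'   between-patient SD (percent).
#' @param measurement_noise_sd echo measurement noise SD (percent).
#' @param control_decline_by_t3 LVEF change (points) in unexposed patients
#'   with no cardiovascular risk burden, by t3.
#' @param exposure_extra_decline_by_t3 additional change attributable to
#'   exposure by t3 (the true average treatment effect at t3).
#' @param decline_fractions fraction of the t3 decline realized at each
#'   timepoint.
#' @param confounder_outcome_effects named LVEF effects (points by t3) of the
#'   confounders, so that naive unweighted comparisons are biased.
#' @param echo_availability per-timepoint probability that a patient has an
#'   echo in that window.
#' @param os_hazard,os_hazard_exposed,censor_rate,rfs_hazard exponential rates
#'   per month for overall survival, censoring, and relapse-free survival.
#' @param cr_rate_intensive,cr_rate_nonintensive complete-remission rates.
#' @param lab_missing_rate missingness rate for the hematologic labs (white
#'   cells, platelets, hemoglobin), which are not assignment covariates.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 363,
                       seed = 1,
                       exposure_prevalence = 65 / 363,
                       idh1_fraction = 26 / 65,
                       assignment_coefficients = c(age_std = 0.25,
                                                   cad = 1.4,
                                                   cv_risk_high = 0.9,
                                                   heart_failure = 0.6,
                                                   valvular_disease = 0.5,
                                                   acei_arb = 0.3,
                                                   beta_blocker = 0.3),
                       lvef_t0_mean = 58.5,
                       lvef_between_sd = 6,
                       measurement_noise_sd = 4,
                       control_decline_by_t3 = -3.1,
                       exposure_extra_decline_by_t3 = -13.5,
                       decline_fractions = c(t0 = 0, t1 = 0.35, t2 = 0.7, t3 = 1),
                       confounder_outcome_effects = c(cad = -4,
                                                      cv_risk_high = -2.5,
                                                      age_std = -1.5),
                       echo_availability = c(t0 = 0.5, t1 = 0.35,
                                             t2 = 0.35, t3 = 0.4),
                       os_hazard = 0.014,
                       os_hazard_exposed = 0.014,
                       censor_rate = 0.0076,
                       rfs_hazard = 0.0294,
                       cr_rate_intensive = 0.664,
                       cr_rate_nonintensive = 0.10,
                       lab_missing_rate = 0.15) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 4,
            cfg$exposure_prevalence > 0, cfg$exposure_prevalence < 1,
            all(cfg$echo_availability >= 0), all(cfg$echo_availability <= 1),
            cfg$lvef_between_sd > 0, cfg$measurement_noise_sd > 0,
            all(names(cfg$decline_fractions) == c("t0", "t1", "t2", "t3")))
  structure(cfg, class = "sim_config")
}

#' True average treatment effect at a timepoint
#'
#' The configured exposure effect on LVEF at one timepoint: the per-timepoint
#' decline fraction times the extra decline attributable to exposure by t3.
#' Since exposed and control patients share the same baseline distribution, it
#' equals the true exposed-minus-control group difference at that timepoint
#' (0 at t0, -13.5 points at t3 under the defaults).
#'
#' @param config a [sim_config()].
#' @param timepoint `"t0"`, `"t1"`, `"t2"` or `"t3"`.
#' @return Effect in LVEF percentage points.
#' @export
true_ate <- function(config, timepoint) {
  stopifnot(inherits(config, "sim_config"))
  if (!(timepoint %in% names(config$decline_fractions)))
    stop("unknown timepoint: ", timepoint)
  unname(config$decline_fractions[timepoint] * config$exposure_extra_decline_by_t3)
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic AML cohort
#'
#' Draws baseline covariates (age truncated-normal on [18, 90], binary
#' comorbidities with age-linked prevalences, lognormal blood counts), assigns
#' exposure by a logistic model whose intercept is calibrated so the realized
#' assignment probabilities average to the configured prevalence (confounding
#' by construction), builds per-patient LVEF trajectories (random patient
#' intercept + timepoint decline + exposure-by-timepoint interaction +
#' confounder effects + measurement noise) thinned by the per-timepoint echo
#' availability, and draws exponential survival, censoring and remission
#' outcomes. The returned ground truth carries the realized assignment model
#' and the true per-timepoint effects, so estimator bias can be measured.
#'
#' @param config a [sim_config()].
#' @return List with `cohort` (a validated cohort data frame) and `truth`
#'   (assignment intercept and coefficients, true propensity scores, true
#'   per-timepoint effects, and the config).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients

  age <- .rtruncnorm(n, 60, 14, 18, 90)
  age_std <- (age - 60) / 14
  sex <- ifelse(stats::runif(n) < 0.576, "male", "female")
  cad <- stats::runif(n) < stats::plogis(stats::qlogis(0.070) + 0.8 * age_std)
  cv_high <- stats::runif(n) < stats::plogis(stats::qlogis(0.105) + 0.8 * age_std)
  cv_count <- ifelse(cv_high,
                     sample(2:4, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
                     sample(0:1, n, replace = TRUE, prob = c(0.45, 0.55)))
  valvular <- stats::runif(n) < 0.044
  heart_failure <- stats::runif(n) < stats::plogis(stats::qlogis(0.022) + 1.0 * cad)
  acei_arb <- stats::runif(n) < stats::plogis(stats::qlogis(0.16) + 1.2 * cad + 0.8 * cv_high)
  beta_blocker <- stats::runif(n) < stats::plogis(stats::qlogis(0.15) + 1.2 * cad + 0.8 * cv_high)
  mra <- stats::runif(n) < 0.006
  cyto <- sample(c("favorable", "intermediate", "adverse"), n, replace = TRUE,
                 prob = c(0.216, 0.547, 0.237))
  history <- sample(c("de_novo", "secondary", "therapy_related"), n,
                    replace = TRUE, prob = c(0.688, 0.251, 0.061))
  wbc <- stats::rlnorm(n, log(8.6), 1.2)
  platelets <- stats::rlnorm(n, log(55), 0.9)
  hemoglobin <- pmin(pmax(stats::rnorm(n, 9.3, 2), 2.5), 16.6)
  intensive <- stats::runif(n) < 0.822
  anthra <- ifelse(intensive, .rtruncnorm(n, 240, 60, 60, 360), 0)

  # assignment model: calibrate the intercept to the target prevalence
  covs <- list(age_std = age_std, cad = as.numeric(cad),
               cv_risk_high = as.numeric(cv_high),
               heart_failure = as.numeric(heart_failure),
               valvular_disease = as.numeric(valvular),
               acei_arb = as.numeric(acei_arb),
               beta_blocker = as.numeric(beta_blocker))
  coefs <- config$assignment_coefficients
  lp <- rep(0, n)
  for (nm in names(coefs)) {
    if (is.null(covs[[nm]])) stop("assignment coefficient for unknown covariate: ", nm)
    lp <- lp + coefs[[nm]] * covs[[nm]]
  }
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp)) - config$exposure_prevalence,
                       interval = c(-12, 6))$root
  ps_true <- stats::plogis(b0 + lp)
  if (min(ps_true) < 0.01 || max(ps_true) > 0.99)
    warning("near-positivity violation: true assignment probabilities reach [",
            signif(min(ps_true), 2), ", ", signif(max(ps_true), 2), "]")
  exposed <- stats::runif(n) < ps_true
  exposure_group <- ifelse(!exposed, "WT",
                           ifelse(stats::runif(n) < config$idh1_fraction,
                                  "IDH1", "IDH2"))

  # LVEF trajectories on an unbalanced echo panel
  conf_eff <- config$confounder_outcome_effects
  conf_lp <- rep(0, n)
  for (nm in names(conf_eff)) {
    if (is.null(covs[[nm]])) stop("outcome effect for unknown covariate: ", nm)
    conf_lp <- conf_lp + conf_eff[[nm]] * covs[[nm]]
  }
  intercept <- stats::rnorm(n, config$lvef_t0_mean, config$lvef_between_sd)
  month_ranges <- list(t0 = c(-4, 0.4), t1 = c(1, 3.5),
                       t2 = c(4.5, 7.5), t3 = c(8.5, 12))
  echo_months <- vector("list", n)
  echo_lvef <- vector("list", n)
  fr <- config$decline_fractions
  for (i in seq_len(n)) {
    mo <- numeric(0); ef <- numeric(0)
    for (tp in names(fr)) {
      if (stats::runif(1) < config$echo_availability[[tp]]) {
        decline <- fr[[tp]] * (config$control_decline_by_t3 +
                                 conf_lp[i] +
                                 as.numeric(exposed[i]) * config$exposure_extra_decline_by_t3)
        val <- intercept[i] + decline + stats::rnorm(1, 0, config$measurement_noise_sd)
        mo <- c(mo, stats::runif(1, month_ranges[[tp]][1], month_ranges[[tp]][2]))
        ef <- c(ef, pmin(pmax(val, 5), 95))
      }
    }
    echo_months[[i]] <- mo
    echo_lvef[[i]] <- ef
  }

  # survival, censoring, remission
  os_rate <- ifelse(exposed, config$os_hazard_exposed, config$os_hazard)
  t_death <- stats::rexp(n, os_rate)
  t_censor <- stats::rexp(n, config$censor_rate)
  os_time <- pmin(t_death, t_censor)
  os_event <- t_death <= t_censor
  cr_prob <- ifelse(intensive, config$cr_rate_intensive, config$cr_rate_nonintensive)
  cr_achieved <- stats::runif(n) < cr_prob
  cr_time <- ifelse(cr_achieved, stats::runif(n, 1, 3), NA_real_)
  t_rfs <- stats::rexp(n, config$rfs_hazard)
  c_rfs <- stats::rexp(n, config$censor_rate)
  rfs_event <- ifelse(cr_achieved, t_rfs <= c_rfs, NA)
  rfs_time <- ifelse(cr_achieved, cr_time + pmin(t_rfs, c_rfs), NA_real_)

  # hematologic labs carry missingness; assignment covariates are complete
  miss <- function(x) { x[stats::runif(n) < config$lab_missing_rate] <- NA; x }

  cohort <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    exposure_group = exposure_group,
    age = age,
    sex = sex,
    aml_history = history,
    wbc = miss(wbc),
    platelets = miss(platelets),
    hemoglobin = miss(hemoglobin),
    cytogenetic_risk = cyto,
    cad = cad,
    valvular_disease = valvular,
    heart_failure = heart_failure,
    cv_risk_factor_count = cv_count,
    acei_arb = acei_arb,
    beta_blocker = beta_blocker,
    mra = mra,
    anthracycline_dose = anthra,
    intensive_induction = intensive,
    cr_achieved = cr_achieved,
    os_time = os_time,
    os_event = os_event,
    cr_time = cr_time,
    rfs_time = rfs_time,
    rfs_event = rfs_event,
    stringsAsFactors = FALSE
  )
  cohort$echo_months <- echo_months
  cohort$echo_lvef <- echo_lvef
  validate_cohort(cohort)
  class(cohort) <- c("aml_cohort", "data.frame")

  truth <- list(
    assignment_intercept = b0,
    assignment_coefficients = coefs,
    ps_true = ps_true,
    ate = vapply(names(fr), function(tp) true_ate(config, tp), numeric(1)),
    config = config
  )
  list(cohort = cohort, truth = truth)
}
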