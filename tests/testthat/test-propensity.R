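test_that("a single binary covariate reproduces the closed-form 2x2 logistic fit", {
  # exposed: 6/23 positive; control: 17/265 positive
  cohort <- make_2x2_cohort(23, 6, 265, 17)
  fit <- fit_propensity_model(cohort, covariates = "cad", model = "model2")
  slope_expected <- log((6 / 17) / (17 / 248))
  intercept_expected <- log(17 / 248)
  expect_equal(unname(fit$coefficients["cad"]), slope_expected, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]), intercept_expected,
               tolerance = 1e-6)
  expect_true(fit$converged)
  # saturated fit reproduces the cell frequencies
  p <- predict_ps(fit, cohort)
  expect_equal(unname(p[cohort$cad]), rep(6 / 23, 23), tolerance = 1e-8)
  expect_equal(unname(p[!cohort$cad][1]), 17 / 265, tolerance = 1e-8)
})

test_that("an intercept-only model returns the exposure prevalence", {
  cohort <- make_2x2_cohort(65, 0, 298, 0)
  fit <- fit_propensity_model(cohort, covariates = character(0), model = "model2")
  expect_equal(unname(fit$ps), rep(65 / 363, 363), tolerance = 1e-8)
})

test_that("a covariate with identical group distributions gets a zero slope", {
  cohort <- make_2x2_cohort(20, 10, 40, 20)
  fit <- fit_propensity_model(cohort, covariates = "cad", model = "model2")
  expect_equal(unname(fit$coefficients["cad"]), 0, tolerance = 1e-6)
  expect_equal(unname(fit$ps), rep(20 / 60, 60), tolerance = 1e-8)
})

test_that("score equations hold at the optimum", {
  g <- generate_cohort(sim_config(n_patients = 600, seed = 3))
  fit <- fit_propensity_model(g$cohort, model = "model2")
  resid <- as.numeric(fit$exposed) - fit$ps
  expect_lt(abs(sum(resid)), 1e-6)
  des <- cardioipw:::ps_design(g$cohort[match(fit$used_ids, g$cohort$patient_id), ],
                               fit$covariates)
  for (cn in fit$covariate_names) {
    expect_lt(abs(sum(des$X[, cn] * resid)), 1e-6)
  }
})

test_that("separation and constant covariates raise informative errors", {
  sep <- make_2x2_cohort(10, 10, 20, 0)   # cad perfectly predicts exposure
  expect_error(fit_propensity_model(sep, covariates = "cad", model = "model2"),
               "separation")
  const <- make_2x2_cohort(10, 0, 20, 0)
  expect_error(fit_propensity_model(const, covariates = "cad", model = "model2"),
               "constant covariate.*cad")
})

test_that("prediction fails clearly on missing covariates and stays in (0,1)", {
  cohort <- make_2x2_cohort(20, 8, 60, 10)
  fit <- fit_propensity_model(cohort, covariates = "cad", model = "model2")
  newdat <- make_cohort("WT", cad = NA)
  expect_error(predict_ps(fit, newdat), "patient T001 is missing covariate cad")
  p <- predict_ps(fit, cohort)
  expect_true(all(p > 0 & p < 1))
})

test_that("complete-case filtering excludes patients missing a model covariate", {
  cohort <- make_2x2_cohort(20, 8, 60, 10)
  cohort$cad[5] <- NA
  fit <- fit_propensity_model(cohort, covariates = "cad", model = "model2")
  expect_equal(fit$n_used, 79)
  expect_false(cohort$patient_id[5] %in% fit$used_ids)
  # imputation keeps everyone
  fit2 <- fit_propensity_model(cohort, covariates = "cad", model = "model2",
                               impute = TRUE)
  expect_equal(fit2$n_used, 80)
})

test_that("estimated assignment coefficients approach the generating truth", {
  # moderate-n check on the generator's logistic assignment model
  cfg <- sim_config(n_patients = 5000, seed = 21)
  g <- generate_cohort(cfg)
  fit <- fit_propensity_model(
    g$cohort,
    covariates = c("age", "cad", "cv_risk_high", "heart_failure",
                   "valvular_disease", "acei_arb", "beta_blocker"),
    model = "model2")
  # cad has the largest true log-odds (1.4); age enters per 14 years
  expect_equal(unname(fit$coefficients["cad"]),
               unname(cfg$assignment_coefficients["cad"]), tolerance = 0.35)
  expect_equal(unname(fit$coefficients["age"]) * 14,
               unname(cfg$assignment_coefficients["age_std"]), tolerance = 0.25)
})

test_that("a propensity model survives a JSON round trip", {
  cohort <- make_2x2_cohort(20, 8, 60, 10)
  fit <- fit_propensity_model(cohort, covariates = "cad", model = "model2")
  f <- withr::local_tempfile(fileext = ".json")
  write_ps_model(fit, f)
  back <- read_ps_model(f)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(back$ps, fit$ps, tolerance = 1e-12)
  expect_equal(back$model_label, "model2")
})
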