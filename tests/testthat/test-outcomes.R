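test_that("weighted mean and SD follow the frequency-weight convention", {
  s <- weighted_mean_sd(c(50, 60), c(1, 3))
  expect_equal(s$mean, 57.5)
  expect_equal(s$sum_w, 4)
  # unit weights reproduce the ordinary mean and sample SD
  x <- c(55, 60, 62, 48)
  s <- weighted_mean_sd(x)
  expect_equal(s$mean, mean(x))
  expect_equal(s$sd, stats::sd(x))
  expect_equal(weighted_mean_sd(c(50, 50, 50))$sd, 0)
  expect_error(weighted_mean_sd(c(1, 2), c(0.4, 0.5)), "exceed 1")
  expect_error(weighted_mean_sd(c(1, 2), c(2, 0)), "at least two")
})

test_that("the pooled t-test matches the textbook example and t.test", {
  tt <- unpaired_ttest(c(1, 2, 3), c(4, 5, 6), variant = "pooled")
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 0.0214, tolerance = 1e-2)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(tt$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(tt$ci95, as.numeric(ref$conf.int), tolerance = 1e-12)
  # Welch variant against t.test default
  set.seed(15)
  x <- stats::rnorm(12, 1); y <- stats::rnorm(20, 0, 2)
  tw <- unpaired_ttest(x, y)
  rw <- stats::t.test(x, y)
  expect_equal(tw$p_value, rw$p.value, tolerance = 1e-12)
  expect_equal(tw$df, unname(rw$parameter), tolerance = 1e-9)
})

test_that("degenerate and invariance cases behave as specified", {
  same <- unpaired_ttest(c(5, 5), c(5, 5))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$ci95, c(0, 0))
  # doubling all weights leaves the point estimate unchanged
  x <- c(40, 55, 62); y <- c(50, 58, 66, 61)
  w1 <- c(1, 2, 3); w0 <- c(2, 1, 1, 4)
  a <- unpaired_ttest(x, y, w1, w0)
  b <- unpaired_ttest(x, y, 2 * w1, 2 * w0)
  expect_equal(a$mean_difference, b$mean_difference, tolerance = 1e-12)
  # under the ESS convention doubling weights changes nothing at all
  a2 <- unpaired_ttest(x, y, w1, w0, convention = "ess")
  b2 <- unpaired_ttest(x, y, 2 * w1, 2 * w0, convention = "ess")
  expect_equal(a2$p_value, b2$p_value, tolerance = 1e-12)
  # swapping the groups negates the difference and mirrors the interval
  s <- unpaired_ttest(y, x, w0, w1)
  expect_equal(s$mean_difference, -a$mean_difference)
  expect_equal(s$ci95, -rev(a$ci95), tolerance = 1e-12)
})

test_that("timepoint effects: equal weights reproduce the unweighted analysis", {
  g <- generate_cohort(sim_config(n_patients = 400, seed = 16))
  fit <- fit_propensity_model(g$cohort, model = "model2")
  wc <- compute_weights(fit$ps, fit$exposed)
  wc$raw_weight <- 1; wc$weight <- 1
  # restrict the unweighted run to the same complete-case patients
  sub <- g$cohort[match(wc$patient_id, g$cohort$patient_id), ]
  class(sub) <- class(g$cohort)
  w_eff <- timepoint_effects(g$cohort, "model2", wc = wc)
  u_eff <- timepoint_effects(sub, "model2")
  expect_equal(w_eff$mean_difference, u_eff$mean_difference, tolerance = 1e-12)
  expect_equal(w_eff$p_value, u_eff$p_value, tolerance = 1e-12)
})

test_that("negating the exposure labels mirrors the effect", {
  g <- generate_cohort(sim_config(n_patients = 500, seed = 17))
  fit <- fit_propensity_model(g$cohort, model = "model2")
  wc <- compute_weights(fit$ps, fit$exposed)
  flipped <- wc
  flipped$exposed <- !flipped$exposed
  a <- timepoint_effects(g$cohort, "model2", wc = wc)
  b <- timepoint_effects(g$cohort, "model2", wc = flipped)
  expect_equal(b$mean_difference, -a$mean_difference, tolerance = 1e-12)
  expect_equal(b$ci_low, -a$ci_high, tolerance = 1e-12)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
})

test_that("a sparse timepoint is flagged non-estimable, not an error", {
  cohort <- make_cohort(c("IDH2", "WT", "WT", "WT"),
                        echo = list(
                          list(months = c(-1), lvef = c(60)),
                          list(months = c(-1, 10), lvef = c(58, 55)),
                          list(months = c(-2, 9), lvef = c(61, 57)),
                          list(months = c(0, 11), lvef = c(59, 52))))
  eff <- timepoint_effects(cohort, "model2")
  t3 <- eff[eff$timepoint == "t3", ]
  expect_false(t3$estimable)
  expect_true(is.na(t3$p_value))
  t0 <- eff[eff$timepoint == "t0", ]
  expect_false(t0$estimable)   # only one exposed echo at t0
})

test_that("within-group change detects decline in the exposed arm only", {
  g <- generate_cohort(sim_config(n_patients = 2000, seed = 18))
  ch_exp <- within_group_change(g$cohort, "model2", "exposed")
  ch_ctl <- within_group_change(g$cohort, "model2", "control")
  e3 <- ch_exp[ch_exp$timepoint == "t3", ]
  c3 <- ch_ctl[ch_ctl$timepoint == "t3", ]
  # exposed arm: large significant decline; control arm: small decline
  expect_lt(e3$mean_change_vs_t0, -10)
  expect_lt(e3$p_value, 0.001)
  expect_gt(c3$mean_change_vs_t0, -6)
  expect_lt(abs(c3$mean_change_vs_t0 - (-3.1)), 2.5)
  # flat trajectories -> changes near zero
  flat <- make_cohort(rep("WT", 40),
                      echo = lapply(1:40, function(i)
                        list(months = c(-1, 2, 6, 10), lvef = rep(60, 4))))
  ch <- within_group_change(flat, "model2", "control")
  expect_equal(ch$mean_change_vs_t0, rep(0, 3))
})

test_that("significance tiers follow the 0.05/0.01/0.001 convention", {
  expect_equal(cardioipw:::.sig_tier(0.2), "")
  expect_equal(cardioipw:::.sig_tier(0.04), "*")
  expect_equal(cardioipw:::.sig_tier(0.009), "**")
  expect_equal(cardioipw:::.sig_tier(0.0005), "***")
})
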