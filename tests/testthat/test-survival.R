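test_that("the product-limit estimator matches hand computations", {
  # three deaths, no censoring
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$curve$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$median, 2)
  # no events: survival stays at 1, median undefined
  km <- km_estimate(c(4, 8), c(FALSE, FALSE))
  expect_true(all(km$curve$surv == 1))
  expect_true(is.na(km$median))
  # single censored patient: S = 1, at-risk drops at 5
  km <- km_estimate(5, FALSE)
  expect_equal(km$curve$surv, 1)
  expect_equal(km$curve$n_censor, 1)
})

test_that("with zero censoring the KM curve equals the empirical survival", {
  set.seed(25)
  for (i in 1:10) {
    t <- sample(1:20, 15, replace = TRUE)
    km <- km_estimate(t, rep(TRUE, 15))
    emp <- vapply(km$curve$time, function(u) mean(t > u), numeric(1))
    expect_equal(km$curve$surv, emp, tolerance = 1e-12)
    orc <- km_oracle(t, rep(1, 15))
    expect_equal(km$curve$surv[km$curve$n_event > 0], orc$surv, tolerance = 1e-12)
  }
})

test_that("KM with random censoring matches the independent oracle", {
  set.seed(26)
  for (i in 1:15) {
    n <- sample(8:25, 1)
    t <- sample(1:12, n, replace = TRUE)     # forces ties, events-first
    e <- stats::runif(n) < 0.6
    km <- km_estimate(t, e)
    orc <- km_oracle(t, as.numeric(e))
    got <- km$curve[km$curve$n_event > 0, ]
    expect_equal(got$time, orc$time)
    expect_equal(got$surv, orc$surv, tolerance = 1e-12)
  }
})

test_that("horizon rates use the S(t-) convention at exact event times", {
  km <- km_estimate(c(10, 24, 40), c(TRUE, TRUE, TRUE))
  expect_equal(km_rate(km, 5), 1)
  expect_equal(km_rate(km, 24), 2 / 3)   # death at exactly 24 not yet counted
  expect_equal(km_rate(km, 24.01), 1 / 3)
  expect_equal(km_rate(km, 60), 0)
})

test_that("RFS endpoints are measured from documented complete remission", {
  cohort <- make_cohort(c("WT", "IDH2", "WT"),
                        cr_achieved = c(TRUE, TRUE, FALSE),
                        cr_time = c(2, 2, NA),
                        rfs_time = c(10, 14, NA),
                        rfs_event = c(TRUE, TRUE, NA))
  rfs <- rfs_endpoints(cohort)
  expect_equal(nrow(rfs), 2)               # the non-CR patient is excluded
  expect_equal(rfs$time, c(8, 12))         # relapse at 10, death in CR at 14
  expect_true(all(rfs$event))
  bad <- cohort
  bad$cr_time[1] <- NA
  expect_error(rfs_endpoints(bad), "cr_time missing")
})

test_that("the log-rank test matches the hypergeometric oracle", {
  # identical groups -> statistic 0
  t <- c(1, 2, 3, 4); e <- c(1, 1, 0, 1)
  res <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1, tolerance = 1e-10)
  # separated event times, no censoring
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1); g1 <- c(TRUE, TRUE, FALSE, FALSE)
  res <- logrank_test(time, event, ifelse(g1, "A", "B"))
  expect_equal(res$statistic, logrank_oracle(time, event, g1), tolerance = 1e-9)
  expect_equal(res$df, 1)
  # random small datasets
  set.seed(27)
  for (i in 1:15) {
    n <- sample(10:30, 1)
    time <- sample(1:15, n, replace = TRUE)
    event <- stats::runif(n) < 0.7
    g1 <- stats::runif(n) < 0.5
    if (length(unique(g1)) < 2 || sum(event) == 0) next
    res <- logrank_test(time, event, ifelse(g1, "A", "B"))
    expect_equal(res$statistic, logrank_oracle(time, as.numeric(event), g1),
                 tolerance = 1e-8)
  }
  # no events anywhere
  res <- logrank_test(c(1, 2), c(FALSE, FALSE), c("a", "b"))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("under the null the log-rank p-value is roughly uniform", {
  set.seed(28)
  p <- replicate(200, {
    time <- stats::rexp(40, 0.1)
    event <- stats::runif(40) < 0.7
    g <- sample(c("a", "b"), 40, replace = TRUE)
    if (length(unique(g)) < 2) return(NA_real_)
    logrank_test(time, event, g)$p_value
  })
  p <- p[!is.na(p)]
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.12)
  expect_gt(mean(p), 0.4)
  expect_lt(mean(p), 0.6)
})

test_that("reverse KM estimates median follow-up", {
  # everyone censored at 91.2 months -> follow-up 91.2
  expect_equal(reverse_km_followup(rep(91.2, 10), rep(FALSE, 10)), 91.2)
  # half censored at 60, half dead at 10 -> 60
  expect_equal(reverse_km_followup(c(rep(60, 5), rep(10, 5)),
                                   c(rep(FALSE, 5), rep(TRUE, 5))), 60)
  # all dead: no censoring distribution
  expect_true(is.na(reverse_km_followup(c(3, 7, 9), c(TRUE, TRUE, TRUE))))
})

test_that("the KM median converges to ln(2)/lambda for exponential data", {
  set.seed(29)
  lambda <- 0.05
  t <- stats::rexp(2000, lambda)
  cens <- stats::rexp(2000, 0.01)
  km <- km_estimate(pmin(t, cens), t <= cens)
  expect_equal(km$median, log(2) / lambda, tolerance = 0.07)
})
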