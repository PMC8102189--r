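test_that("a well-formed CSV round-trips through write and read", {
  g <- generate_cohort(sim_config(n_patients = 30, seed = 7))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(g$cohort, f)
  back <- read_cohort(f)
  expect_equal(nrow(back), 30)
  expect_equal(back$patient_id, g$cohort$patient_id)
  expect_equal(back$exposure_group, g$cohort$exposure_group)
  expect_equal(back$age, g$cohort$age, tolerance = 1e-12)
  expect_equal(back$cad, g$cohort$cad)
  expect_equal(back$wbc, g$cohort$wbc, tolerance = 1e-12)
  for (i in seq_len(30)) {
    expect_equal(back$echo_months[[i]], g$cohort$echo_months[[i]], tolerance = 1e-12)
    expect_equal(back$echo_lvef[[i]], g$cohort$echo_lvef[[i]], tolerance = 1e-12)
  }
  # second write produces byte-identical files (stable formatting)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("semicolon-encoded echo series parse into measurement vectors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,exposure_group,age,sex,os_time,os_event,echo_months,echo_lvef",
    "A,WT,45,male,10,FALSE,0;10,62;48",
    "B,IDH1,60,female,20,TRUE,,",
    "C,IDH2,70,male,5,FALSE,-1,60"
  ), f)
  cohort <- read_cohort(f)
  expect_equal(nrow(cohort), 3)
  expect_equal(cohort$echo_months[[1]], c(0, 10))
  expect_equal(cohort$echo_lvef[[1]], c(62, 48))
  expect_length(cohort$echo_lvef[[2]], 0)
  expect_true(is.na(cohort$wbc[1]))   # absent optional column -> missing marker
})

test_that("validation rejects bad rows with row-addressed messages", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,exposure_group,age,sex,os_time,os_event",
    "A,WT,45,male,10,FALSE",
    "B,WT,15,male,10,FALSE"
  ), f)
  expect_error(read_cohort(f), "row 2.*patient B.*age")

  dup <- make_cohort(c("WT", "WT"))
  dup$patient_id <- c("X", "X")
  expect_error(validate_cohort(dup), "duplicate patient_id")

  bad_enum <- make_cohort("WT")
  bad_enum$exposure_group <- "IDH3"
  expect_error(validate_cohort(bad_enum), "unknown exposure_group token 'IDH3'")

  bad_lvef <- make_cohort("WT", echo = list(list(months = 1, lvef = 120)))
  expect_error(validate_cohort(bad_lvef), "outside \\(0, 100\\]")

  rfs_no_cr <- make_cohort("WT", rfs_time = 5)
  expect_error(validate_cohort(rfs_no_cr), "cr_achieved is not TRUE")
})

test_that("a missing mandatory column is a schema error; a sidecar schema maps names", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,age,sex,os_time,os_event", "A,45,male,10,FALSE"), f)
  expect_error(read_cohort(f), "schema error.*exposure_group")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,mutation,age,sex,os_time,os_event", "A,WT,45,male,10,FALSE"), f2)
  sidecar <- withr::local_tempfile(fileext = ".json")
  writeLines('{"patient_id": "id", "exposure_group": "mutation"}', sidecar)
  cohort <- read_cohort(f2, schema = sidecar)
  expect_equal(cohort$patient_id, "A")
  expect_equal(cohort$exposure_group, "WT")
})

test_that("timepoint windows must be ordered and disjoint", {
  expect_s3_class(default_windows(), "timepoint_windows")
  expect_error(timepoint_windows(t1 = c(0.5, 5), t2 = c(4, 8)), "disjoint")
  expect_error(timepoint_windows(t0 = c(2, 1)), "lo < hi")
})

test_that("assign_timepoints places echoes into windows", {
  # one echo per window
  a <- assign_timepoints(c(-1, 10), c(60, 45))
  expect_equal(a, c(t0 = 60, t3 = 45))
  # empty series -> empty mapping
  expect_length(assign_timepoints(numeric(0), numeric(0)), 0)
  # two candidates in t2 (window [4, 8), center 6): nearer the center wins
  a <- assign_timepoints(c(4.5, 6.5), c(50, 40))
  expect_equal(unname(a["t2"]), 40)
  # equidistant tie -> earlier measurement
  a <- assign_timepoints(c(5.5, 6.5), c(50, 40))
  expect_equal(unname(a["t2"]), 50)
  # latest-in-window rule
  a <- assign_timepoints(c(4.5, 6.5), c(50, 40), rule = "latest_in_window")
  expect_equal(unname(a["t2"]), 40)
  # measurements outside all windows are dropped
  expect_length(assign_timepoints(c(20, -10), c(50, 60)), 0)
})

test_that("no measurement is ever assigned to two timepoints", {
  set.seed(11)
  w <- default_windows()
  for (rep in 1:50) {
    m <- sort(stats::runif(8, -8, 16))
    v <- stats::runif(8, 30, 70)
    a <- assign_timepoints(m, v, w)
    # each assigned value corresponds to a distinct source measurement whose
    # month lies inside exactly one window
    for (tp in names(a)) {
      src <- m[match(a[tp], v)]
      inside <- vapply(names(w), function(k)
        src >= w[[k]][1] && src < w[[k]][2], logical(1))
      expect_equal(sum(inside), 1)
      expect_equal(names(which(inside)), tp)
    }
  }
})
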