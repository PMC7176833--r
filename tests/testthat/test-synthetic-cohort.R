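test_that("screening flow reproduces enrolment minus exclusions and conserves counts", {
  cohort <- generate_cohort(cohort_config(random_seed = 3L))
  f <- cohort$flow
  expect_identical(f$screened, 2192L)
  expect_identical(f$screen_positive, 425L)
  expect_identical(f$retained, 419L)
  expect_identical(f$retained, f$enrolled - f$excluded)
  expect_true(f$screened >= f$screen_positive)
  expect_true(f$screen_positive >= f$enrolled)
  expect_true(f$enrolled >= f$retained)

  # flow conservation holds for arbitrary configs too
  for (args in list(c(100L, 40L, 0L), c(50L, 50L, 10L), c(9L, 3L, 1L))) {
    f2 <- generate_cohort(cohort_config(n_screened = args[1],
                                        n_screen_positive = args[2],
                                        n_excluded = args[3],
                                        random_seed = 1L))$flow
    expect_identical(f2$retained, f2$enrolled - f2$excluded)
    expect_true(f2$screened >= f2$screen_positive && f2$enrolled >= f2$retained)
  }
})

test_that("zero attrition gives exactly four wave records per participant", {
  cohort <- generate_cohort(tiny_cohort_config(attrition_rate_per_wave = 0))
  waves_per_id <- table(cohort$records$participant_id)
  expect_true(all(waves_per_id == 4L))
})

test_that("attrition is monotone: absence at a wave implies absence later", {
  cohort <- generate_cohort(tiny_cohort_config(n_positive = 206L,
                                               attrition_rate_per_wave = 0.3,
                                               seed = 5L))
  by_id <- split(cohort$records$wave, cohort$records$participant_id)
  for (w in by_id) expect_identical(sort(w), seq_len(length(w)))
})

test_that("identical config and seed give identical cohorts", {
  a <- generate_cohort(tiny_cohort_config(seed = 7L))
  b <- generate_cohort(tiny_cohort_config(seed = 7L))
  expect_identical(a$records, b$records)
  expect_identical(a$flow, b$flow)
  c2 <- generate_cohort(tiny_cohort_config(seed = 8L))
  expect_false(identical(a$records, c2$records))
})

test_that("depression status uses strict > cutoff and flags missing as unknown", {
  expect_true(assign_depression_status(9))
  expect_false(assign_depression_status(8))
  expect_false(assign_depression_status(0))
  expect_identical(assign_depression_status(NA_integer_), NA)
  expect_true(assign_depression_status(11, cutoff = 10))
  expect_error(assign_depression_status(-1), "hrsd")
})

test_that("generated HRSD scores are consistent with per-wave status draws", {
  cohort <- generate_cohort(tiny_cohort_config(n_positive = 406L, seed = 2L))
  rec <- cohort$records
  status <- assign_depression_status(rec$hrsd_score)
  # wave-1 prevalence near the configured 403/419
  w1 <- status[rec$wave == 1L]
  expect_gt(mean(w1), 0.9)
  # later waves have a substantial non-depressed fraction
  w4 <- status[rec$wave == 4L]
  expect_lt(mean(w4), 0.75)
  expect_gt(mean(w4), 0.3)
})

test_that("utilisation means are recovered at large n within 3 Monte Carlo SEs", {
  cfg <- cohort_config(n_screened = 12000L, n_screen_positive = 5006L,
                       n_excluded = 6L, attrition_rate_per_wave = 0,
                       depression_prevalence_by_wave = rep(1, 4),
                       random_seed = 41L)
  cohort <- generate_cohort(cfg)
  w1 <- cohort$records[cohort$records$wave == 1L, ]
  n <- nrow(w1)
  for (svc in c("clinic_visits_3m", "opd_visits_3m", "inpatient_days_6m",
                "child_inpatient_days_6m")) {
    pars <- cfg$utilisation[[svc]]
    mu <- pars$mean[["depressed"]]
    se <- sqrt(mu + mu^2 / pars$dispersion) / sqrt(n)
    expect_lt(abs(mean(w1[[svc]]) - mu), 3 * se)
  }
})

test_that("invalid configurations are rejected with configuration errors", {
  expect_error(cohort_config(n_screened = -1), "configuration error")
  expect_error(cohort_config(n_screen_positive = 10.5), "configuration error")
  expect_error(cohort_config(n_screen_positive = 5000L), "exceed")
  expect_error(cohort_config(n_excluded = 500L), "exceed")
  expect_error(cohort_config(attrition_rate_per_wave = 1.2), "configuration error")
  expect_error(cohort_config(depression_prevalence_by_wave = c(0.5, 0.5)), "length 4")
  expect_error(cohort_config(income_category_probs = rbind(c(1, 1, 1, 1, 1),
                                                           c(0.2, 0.2, 0.2, 0.2, 0.2))),
               "sum to 1")
})

test_that("an attrition-emptied group cell is logged, not fatal", {
  cfg <- tiny_cohort_config(n_positive = 16L, excluded = 0L, seed = 9L,
                            depression_prevalence_by_wave = c(1, 1, 1, 1))
  cohort <- generate_cohort(cfg)
  expect_true(any(grepl("empty non-depressed cell", cohort$log)))
})

test_that("cohort CSV and flow JSON round-trip through disk", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(tiny_cohort_config(seed = 13L))
  paths <- write_cohort(cohort, dir)
  expect_true(all(file.exists(paths)))
  back <- read_cohort(paths[["cohort"]])
  expect_equal(nrow(back$records), nrow(cohort$records))
  expect_identical(back$flow$retained, cohort$flow$retained)
  flow <- jsonlite::read_json(paths[["flow"]])
  expect_identical(flow$retained, cohort$flow$retained)
})
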