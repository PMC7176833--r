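test_that("the perinatal structure is 4 states over 7 cycles (21 months)", {
  spec <- build_perinatal_spec("depressed", "provider", "mother")
  expect_identical(spec$states$name,
                   c("antenatal_0_6m", "antenatal_6_9m", "postnatal_0_3m",
                     "postnatal_3_12m"))
  expect_identical(spec$states$n_cycles, c(2L, 1L, 1L, 3L))
  expect_identical(sum(spec$states$n_cycles), 7L)
  expect_identical(sum(spec$states$n_cycles) * spec$cycle_length_months, 21L)
  expect_identical(spec$states$source_wave, 1:4)
})

test_that("provider cycle costs multiply counts by unit costs with the halving and spreading rules", {
  uc <- toy_unit_costs()
  rec <- toy_record(clinic_visits_3m = 2L)
  cc <- state_cycle_costs(rec, "antenatal_0_6m", "depressed", "provider",
                          "mother", uc)
  expect_equal(cc$cost, 2 * 10)

  # 4 inpatient days over the 6-month recall halve to a 3-month cycle
  rec2 <- toy_record(inpatient_days_6m = 4L)
  cc2 <- state_cycle_costs(rec2, "antenatal_0_6m", "depressed", "provider",
                           "mother", toy_unit_costs(ipd = 50))
  expect_equal(cc2$cost, 100)

  # 9 antenatal visits spread over the 3 antenatal cycles
  rec3 <- rbind(toy_record(),
                toy_record(wave = 2L, antenatal_visits_total = 9L))
  for (st in c("antenatal_0_6m", "antenatal_6_9m")) {
    cc3 <- state_cycle_costs(rec3, st, "depressed", "provider", "mother", uc)
    expect_equal(cc3$cost, 9 * 10 / 3)
  }
  # and none of it reaches the postnatal states
  rec3b <- rbind(rec3, toy_record(wave = 3L, delivery_site = "MOU",
                                  delivery_days = 0L),
                 toy_record(wave = 4L, wellbaby_visits_total = 0L))
  cc3b <- state_cycle_costs(rec3b, "postnatal_3_12m", "depressed", "provider",
                            "mother", uc)
  expect_equal(cc3b$cost, 0)
})

test_that("delivery costs enter the 0-3 months postnatal state at the site rate", {
  uc <- toy_unit_costs(mou = 100, hosp = 200)
  recs <- rbind(
    toy_record(participant_id = "A", wave = 3L, delivery_site = "MOU",
               delivery_days = 2L),
    toy_record(participant_id = "B", wave = 3L, delivery_site = "hospital",
               delivery_days = 3L)
  )
  cc <- state_cycle_costs(recs, "postnatal_0_3m", "depressed", "provider",
                          "mother", uc)
  expect_equal(cc$cost[cc$participant_id == "A"], 200)
  expect_equal(cc$cost[cc$participant_id == "B"], 600)
  # the child model carries no delivery cost
  ccc <- state_cycle_costs(recs, "postnatal_0_3m", "depressed", "provider",
                           "child", uc)
  expect_equal(ccc$cost, c(0, 0))
})

test_that("well-baby totals spread over the 4 postnatal cycles of the child model", {
  uc <- toy_unit_costs(clinic = 10)
  recs <- rbind(toy_record(wave = 3L, delivery_site = "MOU", delivery_days = 0L),
                toy_record(wave = 4L, wellbaby_visits_total = 8L))
  for (st in c("postnatal_0_3m", "postnatal_3_12m")) {
    cc <- state_cycle_costs(recs, st, "depressed", "provider", "child", uc)
    expect_equal(cc$cost, 8 * 10 / 4)
  }
  cc_ante <- state_cycle_costs(recs[2, ], "postnatal_3_12m", "depressed",
                               "provider", "mother", uc)
  expect_equal(cc_ante$cost, 0)
})

test_that("group summaries average within the wave's depression group and flag empty cells", {
  uc <- toy_unit_costs()
  recs <- rbind(
    toy_record(participant_id = "A", hrsd_score = 20L, clinic_visits_3m = 4L),
    toy_record(participant_id = "B", hrsd_score = 15L, clinic_visits_3m = 2L),
    toy_record(participant_id = "C", hrsd_score = 2L, clinic_visits_3m = 1L)
  )
  s <- state_cost_summary(recs, "antenatal_0_6m", "depressed", "provider",
                          "mother", uc)
  expect_equal(s$cost_mean, 30)
  expect_equal(s$cost_sd, stats::sd(c(40, 20)))
  expect_identical(s$n, 2L)
  s2 <- state_cost_summary(recs, "antenatal_0_6m", "non_depressed", "provider",
                           "mother", uc)
  expect_equal(s2$cost_mean, 10)
  expect_error(state_cost_summary(recs[3, ], "antenatal_0_6m", "depressed",
                                  "provider", "mother", uc),
               "empty cell")
})

test_that("deterministic totals are cycle-weighted sums, linear in state means", {
  expect_equal(deterministic_total(manual_spec(c(10, 10, 10, 10))), 70)
  expect_equal(deterministic_total(manual_spec(c(0, 0, 0, 0))), 0)
  expect_equal(deterministic_total(manual_spec(c(100, 120, 300, 80))), 860)
  expect_error(deterministic_total(build_perinatal_spec()), "unpopulated")

  set.seed(71)
  m <- runif(4, 0, 500)
  a <- deterministic_total(manual_spec(m))
  b <- deterministic_total(manual_spec(2 * m))
  d <- runif(4, 0, 100)
  expect_equal(b, 2 * a, tolerance = 1e-12)
  expect_equal(deterministic_total(manual_spec(m + d)),
               a + deterministic_total(manual_spec(d)), tolerance = 1e-9)
})

test_that("gamma parameters reproduce the input moments", {
  g <- gamma_from_moments(4, 2)
  expect_equal(g$shape, 4)
  expect_equal(g$scale, 1)
  g2 <- gamma_from_moments(3, 6)
  expect_equal(g2$shape, 0.25)
  expect_equal(g2$scale, 12)
  expect_equal(g2$shape * g2$scale, 3)
  expect_equal(g2$shape * g2$scale^2, 36)
  d <- gamma_from_moments(5, 0)
  expect_true(d$degenerate)
  expect_equal(d$mean, 5)
  z <- gamma_from_moments(0, 0)
  expect_true(z$degenerate)
  expect_error(gamma_from_moments(-1, 2), "gamma undefined")
  expect_error(gamma_from_moments(0, 2), "gamma undefined")
})

test_that("PSA collapses to the deterministic total when all sds are zero", {
  spec <- manual_spec(c(100, 120, 300, 80))
  res <- run_psa(spec, n_iterations = 500, seed = 4)
  expect_equal(res$psa_mean, 860)
  expect_equal(res$ui_lower, 860)
  expect_equal(res$ui_upper, 860)
  expect_equal(res$deterministic_total, 860)
})

test_that("PSA means are unbiased and intervals bracket the mean", {
  spec <- manual_spec(c(100, 120, 300, 80), sds = c(40, 60, 150, 30))
  res <- run_psa(spec, n_iterations = 10000, seed = 9, keep_draws = TRUE)
  mc_se <- stats::sd(res$draws) / sqrt(res$n_iterations)
  expect_lt(abs(res$psa_mean - res$deterministic_total), 3 * mc_se)
  expect_lte(res$ui_lower, res$psa_mean)
  expect_lte(res$psa_mean, res$ui_upper)
  # seeded reproducibility
  res2 <- run_psa(spec, n_iterations = 10000, seed = 9)
  expect_equal(res2$psa_mean, res$psa_mean)
  expect_equal(res2$ui_lower, res$ui_lower)
})

test_that("a single-state model reproduces closed-form gamma quantiles", {
  spec <- manual_spec(c(4, 0, 0, 0), sds = c(2, 0, 0, 0))
  spec$states$n_cycles <- c(1L, 0L, 0L, 0L)
  # per-cycle cost ~ gamma(shape 4, scale 1)
  res <- run_psa(spec, n_iterations = 10000, seed = 12, keep_draws = TRUE)
  expect_equal(res$ui_lower, stats::qgamma(0.05, 4, scale = 1), tolerance = 0.05)
  expect_equal(res$ui_upper, stats::qgamma(0.95, 4, scale = 1), tolerance = 0.05)
})

test_that("UI width shrinks as the sd inputs shrink", {
  wide <- run_psa(manual_spec(c(100, 120, 300, 80), sds = c(40, 60, 150, 30)),
                  n_iterations = 4000, seed = 5)
  narrow <- run_psa(manual_spec(c(100, 120, 300, 80), sds = c(4, 6, 15, 3)),
                    n_iterations = 4000, seed = 5)
  expect_lt(narrow$ui_upper - narrow$ui_lower, wide$ui_upper - wide$ui_lower)
})

test_that("mother and child models are independent of each other's inputs", {
  uc <- toy_unit_costs()
  make_recs <- function(child_clinic) rbind(
    toy_record(participant_id = "A", clinic_visits_3m = 2L,
               child_clinic_visits_3m = child_clinic),
    toy_record(participant_id = "A", wave = 2L, antenatal_visits_total = 6L),
    toy_record(participant_id = "A", wave = 3L, delivery_site = "MOU",
               delivery_days = 1L),
    toy_record(participant_id = "A", wave = 4L, wellbaby_visits_total = 4L)
  )
  spec <- build_perinatal_spec("depressed", "provider", "mother")
  a <- deterministic_total(populate_markov_spec(spec, make_recs(0L), uc))
  b <- deterministic_total(populate_markov_spec(spec, make_recs(50L), uc))
  expect_equal(a, b)
  specc <- build_perinatal_spec("depressed", "provider", "child")
  ca <- deterministic_total(populate_markov_spec(specc, make_recs(0L), uc))
  cb <- deterministic_total(populate_markov_spec(specc, make_recs(50L), uc))
  expect_gt(cb, ca)
})
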