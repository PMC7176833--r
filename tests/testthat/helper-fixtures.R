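# Small configs and hand-built records shared across test files.

tiny_cohort_config <- function(n_positive = 56L, excluded = 6L, seed = 11L, ...) {
  cohort_config(n_screened = n_positive + 250L, n_screen_positive = n_positive,
                n_excluded = excluded, random_seed = seed, ...)
}

# a unit-cost table with easy round numbers
toy_unit_costs <- function(clinic = 10, opd = 5, ipd = 50, mou = 100, hosp = 200) {
  structure(list(
    cost_per_clinic_visit = clinic,
    cost_per_opd_visit = opd,
    cost_per_inpatient_day = ipd,
    cost_per_delivery_day_mou = mou,
    cost_per_delivery_day_hospital = hosp,
    currency = "ZAR", price_year = "2014/15", zar_per_usd = 11.69
  ), class = "unit_cost_table")
}

# one hand-written participant x wave record with every field the costing
# path reads; overrides are applied on top
toy_record <- function(...) {
  rec <- data.frame(
    participant_id = "P1", wave = 1L, hrsd_score = 12L,
    employed = FALSE, has_partner = TRUE,
    income_category = "0-1000", household_size = 4L,
    dwelling_formal = TRUE, owns_dwelling = TRUE, electricity = TRUE,
    piped_water = TRUE, income_source_fixed = FALSE, bank_account = TRUE,
    food_shop_supermarket = TRUE, education = "some_secondary",
    clinic_visits_3m = 0L, opd_visits_3m = 0L, inpatient_days_6m = 0L,
    antenatal_visits_total = NA_integer_, delivery_site = NA_character_,
    delivery_days = NA_integer_, wellbaby_visits_total = NA_integer_,
    child_clinic_visits_3m = 0L, child_opd_visits_3m = 0L,
    child_inpatient_days_6m = 0L,
    travel_minutes = 0, wait_minutes = 0, consult_minutes = 0,
    travel_cost_zar = 0, user_fees_zar = 0,
    child_travel_cost_zar = 0, child_user_fees_zar = 0,
    stringsAsFactors = FALSE
  )
  ov <- list(...)
  for (nm in names(ov)) rec[[nm]] <- ov[[nm]]
  rec
}

# populated markov spec with given state means/sds, bypassing the cohort
manual_spec <- function(means, sds = rep(0, 4), group = "depressed",
                        perspective = "provider", person = "mother") {
  spec <- build_perinatal_spec(group, perspective, person)
  spec$states$cost_mean <- means
  spec$states$cost_sd <- sds
  spec$states$n <- 100L
  spec
}
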