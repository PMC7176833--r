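#' Opportunity-cost valuation of care-seeking time
#'
#' The mother's time spent travelling to, waiting at and consulting in health
#' facilities is valued at forgone earnings. To value time equitably across
#' the cohort, a single hourly rate is derived from the mean baseline
#' per-capita household income, assuming 228 working days per year and 8
#' working hours per day.
#'
#' @param baseline_mean_per_capita_income_monthly Mean monthly per-capita
#'   household income at baseline (money, > 0).
#' @param working_days_per_year Assumed working days per annum (default 228).
#' @param working_hours_per_day Assumed working hours per day (default 8).
#' @return An object of class `time_valuation` with the derived `hourly_rate`.
#' @export
#' @examples
#' time_valuation(152)$hourly_rate # 152 * 12 / (228 * 8) = 1
time_valuation <- function(baseline_mean_per_capita_income_monthly,
                           working_days_per_year = 228L,
                           working_hours_per_day = 8) {
  assert_pos(baseline_mean_per_capita_income_monthly,
             "baseline_mean_per_capita_income_monthly")
  assert_pos(working_days_per_year, "working_days_per_year")
  assert_pos(working_hours_per_day, "working_hours_per_day")
  rate <- baseline_mean_per_capita_income_monthly * 12 /
    (working_days_per_year * working_hours_per_day)
  structure(list(
    baseline_mean_per_capita_income_monthly = baseline_mean_per_capita_income_monthly,
    working_days_per_year = working_days_per_year,
    working_hours_per_day = working_hours_per_day,
    hourly_rate = rate
  ), class = "time_valuation")
}

#' Hourly opportunity-cost rate
#'
#' @param valuation A [time_valuation()] object.
#' @return Money per hour.
#' @export
hourly_opportunity_rate <- function(valuation) {
  valuation$hourly_rate
}

#' Patient cost of a single ambulatory visit
#'
#' Sums out-of-pocket travel expenses, user fees, and the opportunity cost of
#' the mother's travel, waiting and consultation time. For a child's visit
#' the time valued is the mother's accompanying time at the same rate; the
#' child's own time carries no opportunity cost (children do not work), so
#' `is_child_visit` does not change the arithmetic — it is accepted to make
#' the exclusion explicit at call sites.
#'
#' @param travel_minutes,wait_minutes,consult_minutes Minutes spent per
#'   visit (the mother's time, also when accompanying a child).
#' @param travel_cost Out-of-pocket travel expense for the visit.
#' @param user_fee User fee paid for the visit.
#' @param rate Hourly opportunity-cost rate.
#' @param is_child_visit Whether the visit is for the child(ren).
#' @return Money cost of the visit.
#' @export
#' @examples
#' ambulatory_visit_cost(30, 60, 30, travel_cost = 3, user_fee = 0, rate = 0.5)
ambulatory_visit_cost <- function(travel_minutes, wait_minutes, consult_minutes,
                                  travel_cost, user_fee, rate,
                                  is_child_visit = FALSE) {
  for (nm in c("travel_minutes", "wait_minutes", "consult_minutes",
               "travel_cost", "user_fee", "rate")) {
    assert_nonneg(get(nm), nm)
  }
  hours <- (travel_minutes + wait_minutes + consult_minutes) / 60
  travel_cost + user_fee + rate * hours
}

#' Patient cost of one participant's 3-month cycle
#'
#' Sums the household cost of all routine ambulatory care in a participant's
#' interview wave: for each mother and child clinic/outpatient visit, the
#' mother's per-visit time at the opportunity-cost rate, plus the recall
#' window's travel expenses and user fees. Delivery and inpatient episodes
#' contribute money costs only (their travel and fees sit in the window
#' totals): no opportunity cost of time is attached to them, since those
#' times would largely fall outside working hours. Antenatal and well-baby
#' visit totals are not included here; they enter the model through the
#' spreading rule applied by the Markov engine.
#'
#' @param record One row of a cohort `records` table (one participant x wave).
#' @param rate Hourly opportunity-cost rate.
#' @param person `"mother"` for the woman's own care, `"child"` for her
#'   child(ren)'s care (costed as the mother's accompanying time plus the
#'   child-visit travel/fees).
#' @return Money cost for the 3-month cycle.
#' @export
period_patient_cost <- function(record, rate, person = c("mother", "child")) {
  person <- match.arg(person)
  per_visit_hours <- (record$travel_minutes + record$wait_minutes +
                        record$consult_minutes) / 60
  if (person == "mother") {
    visits <- record$clinic_visits_3m + record$opd_visits_3m
    money <- record$travel_cost_zar + record$user_fees_zar
  } else {
    visits <- record$child_clinic_visits_3m + record$child_opd_visits_3m
    money <- record$child_travel_cost_zar + record$child_user_fees_zar
  }
  assert_nonneg(visits, "visit counts")
  assert_nonneg(money, "money amounts")
  money + rate * visits * per_visit_hours
}

#' Share of per-capita household income spent accessing care
#'
#' @param patient_cost_total Household care-seeking cost over a horizon.
#' @param per_capita_income_total Per-capita household income over the same
#'   horizon; must be > 0 (participants with non-positive income are excluded
#'   from share statistics upstream).
#' @param catastrophic_threshold Share above which spending is flagged
#'   catastrophic (default 0.10, a conventional threshold).
#' @return List with `share` and logical `catastrophic`.
#' @export
#' @examples
#' cost_income_share(11, 100) # share 0.11, catastrophic at the 10% threshold
cost_income_share <- function(patient_cost_total, per_capita_income_total,
                              catastrophic_threshold = 0.10) {
  assert_nonneg(patient_cost_total, "patient_cost_total")
  if (any(per_capita_income_total <= 0))
    stop_config("validation error: per_capita_income_total must be > 0")
  share <- patient_cost_total / per_capita_income_total
  list(share = share, catastrophic = share > catastrophic_threshold)
}
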