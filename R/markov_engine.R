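#' The four perinatal Markov states
#'
#' The model runs on a 3-month cycle over a 21-month horizon: participants
#' enter at 0-6 months antenatal (2 cycles), move to 6-9 months antenatal
#' (1 cycle), then 0-3 months postnatal (1 cycle, carrying delivery costs),
#' and finally 3-12 months postnatal (3 cycles). Each state's per-cycle cost
#' is populated from the interview wave covering that period. There is no
#' absorbing state; every participant traverses all four states.
#'
#' @return Data frame with `name`, `source_wave`, `n_cycles`.
#' @export
perinatal_states <- function() {
  data.frame(
    name = c("antenatal_0_6m", "antenatal_6_9m", "postnatal_0_3m", "postnatal_3_12m"),
    source_wave = 1:4,
    n_cycles = c(2L, 1L, 1L, 3L),
    stringsAsFactors = FALSE
  )
}

N_ANTENATAL_CYCLES <- 3L  # 2 + 1: divisor for spreading total antenatal visits
N_POSTNATAL_CYCLES <- 4L  # 1 + 3: divisor for spreading total well-baby visits

#' Build a perinatal Markov model specification
#'
#' One model per combination of depression group, costing perspective and
#' person; per-cycle cost moments are filled in by [populate_markov_spec()].
#'
#' @param group `"depressed"` or `"non_depressed"`.
#' @param perspective `"provider"` (public health services) or `"patient"`
#'   (household time, travel, fees).
#' @param person `"mother"` or `"child"`.
#' @return An object of class `markov_spec` with the fixed 4-state,
#'   2/1/1/3-cycle structure and `cost_mean`/`cost_sd` set to `NA` until
#'   populated.
#' @export
build_perinatal_spec <- function(group = c("depressed", "non_depressed"),
                                 perspective = c("provider", "patient"),
                                 person = c("mother", "child")) {
  group <- match.arg(group)
  perspective <- match.arg(perspective)
  person <- match.arg(person)
  states <- perinatal_states()
  states$cost_mean <- NA_real_
  states$cost_sd <- NA_real_
  states$n <- NA_integer_
  structure(list(states = states, cycle_length_months = 3L,
                 group = group, perspective = perspective, person = person),
            class = "markov_spec")
}

#' @export
print.markov_spec <- function(x, ...) {
  cat(sprintf("Perinatal Markov model: %s / %s / %s (%d-month cycles, %d cycles)\n",
              x$group, x$perspective, x$person, x$cycle_length_months,
              sum(x$states$n_cycles)))
  print(x$states)
  invisible(x)
}

# attach each participant's wave-2 antenatal total and wave-4 well-baby total
# to every one of their rows, so spread costs can enter antenatal and
# postnatal states sourced from other waves
augment_spread_totals <- function(records) {
  w2 <- records[records$wave == 2L, c("participant_id", "antenatal_visits_total")]
  names(w2)[2] <- "anc_total"
  w4 <- records[records$wave == 4L, c("participant_id", "wellbaby_visits_total")]
  names(w4)[2] <- "wellbaby_total"
  out <- merge(records, w2, by = "participant_id", all.x = TRUE)
  out <- merge(out, w4, by = "participant_id", all.x = TRUE)
  out[order(out$participant_id, out$wave), ]
}

#' Per-participant cycle costs for one Markov state
#'
#' Computes each retained participant's 3-month cycle cost for the given
#' state, perspective and person, before group averaging. Costing rules:
#' \itemize{
#'   \item Provider: ambulatory counts times unit costs; inpatient days
#'     (6-month recall) halved to the 3-month cycle; total antenatal visits
#'     spread evenly over the 3 antenatal cycles (mother, clinic rate); total
#'     well-baby visits spread over the 4 postnatal cycles (child, clinic
#'     rate); delivery days times the site's delivery-day rate, in the
#'     0-3 months postnatal state only (mother).
#'   \item Patient: travel expenses and user fees for the recall window plus
#'     the mother's per-visit time at the opportunity-cost rate; no time cost
#'     for delivery or inpatient care; spread antenatal/well-baby visits
#'     carry time costs at the state's per-visit times.
#' }
#' Participants missing a spread total (lost before wave 2 or 4) are imputed
#' the group mean of the observed totals.
#'
#' @param records Cohort records augmented by the internal spread join (a
#'   plain cohort `records` table is accepted and augmented on the fly).
#' @param state_name One of the four state names in [perinatal_states()].
#' @param group,perspective,person Model coordinates as in
#'   [build_perinatal_spec()].
#' @param unit_costs A `unit_cost_table`.
#' @param rate Hourly opportunity-cost rate (patient perspective).
#' @param hrsd_cutoff Depression cutoff applied at the state's source wave.
#' @return Data frame with `participant_id`, component columns and `cost`.
#' @export
state_cycle_costs <- function(records, state_name, group, perspective, person,
                              unit_costs, rate = 0, hrsd_cutoff = 8L) {
  states <- perinatal_states()
  if (!state_name %in% states$name)
    stop_config("unknown Markov state '%s'", state_name)
  if (!"anc_total" %in% names(records))
    records <- augment_spread_totals(records)
  w <- states$source_wave[states$name == state_name]
  rows <- records[records$wave == w, , drop = FALSE]
  status <- assign_depression_status(rows$hrsd_score, hrsd_cutoff)
  rows <- rows[!is.na(status), , drop = FALSE]
  status <- status[!is.na(status)]
  rows <- rows[if (group == "depressed") status else !status, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop_config("empty cell: no %s participants at state %s (wave %d)",
                group, state_name, w)

  impute_mean <- function(x) {
    if (all(is.na(x))) return(rep(0, length(x)))
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  }
  antenatal_state <- state_name %in% c("antenatal_0_6m", "antenatal_6_9m")
  postnatal_state <- state_name %in% c("postnatal_0_3m", "postnatal_3_12m")
  out <- data.frame(participant_id = rows$participant_id,
                    stringsAsFactors = FALSE)

  if (perspective == "provider") {
    uc <- unit_costs
    if (person == "mother") {
      out$ambulatory <- rows$clinic_visits_3m * uc$cost_per_clinic_visit +
        rows$opd_visits_3m * uc$cost_per_opd_visit
      out$inpatient <- rows$inpatient_days_6m / 2 * uc$cost_per_inpatient_day
      out$antenatal <- if (antenatal_state) {
        impute_mean(rows$anc_total) / N_ANTENATAL_CYCLES * uc$cost_per_clinic_visit
      } else 0
      out$delivery <- if (state_name == "postnatal_0_3m") {
        rate_site <- ifelse(rows$delivery_site == "hospital",
                            uc$cost_per_delivery_day_hospital,
                            uc$cost_per_delivery_day_mou)
        rows$delivery_days * rate_site
      } else 0
      out$wellbaby <- 0
    } else {
      out$ambulatory <- rows$child_clinic_visits_3m * uc$cost_per_clinic_visit +
        rows$child_opd_visits_3m * uc$cost_per_opd_visit
      out$inpatient <- rows$child_inpatient_days_6m / 2 * uc$cost_per_inpatient_day
      out$antenatal <- 0
      out$delivery <- 0
      out$wellbaby <- if (postnatal_state) {
        impute_mean(rows$wellbaby_total) / N_POSTNATAL_CYCLES * uc$cost_per_clinic_visit
      } else 0
    }
  } else {
    per_visit_hours <- (rows$travel_minutes + rows$wait_minutes +
                          rows$consult_minutes) / 60
    if (person == "mother") {
      visits <- rows$clinic_visits_3m + rows$opd_visits_3m
      out$time <- rate * visits * per_visit_hours
      out$travel <- rows$travel_cost_zar
      out$fees <- rows$user_fees_zar
      out$antenatal <- if (antenatal_state) {
        rate * impute_mean(rows$anc_total) / N_ANTENATAL_CYCLES * per_visit_hours
      } else 0
      out$wellbaby <- 0
    } else {
      visits <- rows$child_clinic_visits_3m + rows$child_opd_visits_3m
      out$time <- rate * visits * per_visit_hours
      out$travel <- rows$child_travel_cost_zar
      out$fees <- rows$child_user_fees_zar
      out$antenatal <- 0
      out$wellbaby <- if (postnatal_state) {
        rate * impute_mean(rows$wellbaby_total) / N_POSTNATAL_CYCLES * per_visit_hours
      } else 0
    }
  }
  comp <- setdiff(names(out), "participant_id")
  out$cost <- rowSums(out[, comp, drop = FALSE])
  if (any(out$cost < 0))
    stop_config("validation error: negative cycle cost encountered")
  out
}

#' Per-cycle cost moments for one Markov state
#'
#' @inheritParams state_cycle_costs
#' @return List with `cost_mean`, `cost_sd`, `n` (sample mean and standard
#'   deviation across the state's group participants).
#' @export
state_cost_summary <- function(records, state_name, group, perspective, person,
                               unit_costs, rate = 0, hrsd_cutoff = 8L) {
  cc <- state_cycle_costs(records, state_name, group, perspective, person,
                          unit_costs, rate, hrsd_cutoff)
  list(cost_mean = mean(cc$cost),
       cost_sd = if (nrow(cc) > 1L) stats::sd(cc$cost) else 0,
       n = nrow(cc))
}

#' Populate a Markov specification from cohort data
#'
#' Fills every state's per-cycle cost mean and standard deviation using
#' [state_cost_summary()].
#'
#' @param spec A [build_perinatal_spec()] object.
#' @param cohort A `perinatal_cohort` (or its `records` data frame).
#' @param unit_costs A `unit_cost_table`.
#' @param rate Hourly opportunity-cost rate (used by the patient
#'   perspective).
#' @param hrsd_cutoff Depression cutoff.
#' @return The spec with `cost_mean`, `cost_sd` and `n` filled in.
#' @export
populate_markov_spec <- function(spec, cohort, unit_costs, rate = 0,
                                 hrsd_cutoff = 8L) {
  records <- if (inherits(cohort, "perinatal_cohort")) cohort$records else cohort
  records <- augment_spread_totals(records)
  for (i in seq_len(nrow(spec$states))) {
    s <- state_cost_summary(records, spec$states$name[i], spec$group,
                            spec$perspective, spec$person, unit_costs,
                            rate, hrsd_cutoff)
    spec$states$cost_mean[i] <- s$cost_mean
    spec$states$cost_sd[i] <- s$cost_sd
    spec$states$n[i] <- s$n
  }
  spec
}

#' Deterministic total cost over the model horizon
#'
#' The sum over states of the per-cycle cost mean times the number of cycles
#' spent in the state. No discounting and no half-cycle correction are
#' applied over the 21-month horizon.
#'
#' @param spec A populated `markov_spec`.
#' @return Total cost (same currency as the state means).
#' @export
deterministic_total <- function(spec) {
  if (anyNA(spec$states$cost_mean))
    stop_config("unpopulated state(s): %s",
                paste(spec$states$name[is.na(spec$states$cost_mean)], collapse = ", "))
  sum(spec$states$cost_mean * spec$states$n_cycles)
}

#' Gamma parameters from a mean and standard deviation
#'
#' Method-of-moments mapping used for probabilistic sensitivity analysis:
#' `shape = mean^2 / sd^2`, `scale = sd^2 / mean`, so that
#' `shape * scale = mean` and `shape * scale^2 = sd^2` exactly. A zero
#' standard deviation (or a zero mean) yields a degenerate point mass.
#'
#' @param mean Cost mean (>= 0; must be > 0 when `sd` > 0).
#' @param sd Cost standard deviation (>= 0).
#' @return An object of class `gamma_params`: `shape`, `scale`, `mean`,
#'   `sd`, `degenerate`.
#' @export
#' @examples
#' gamma_from_moments(4, 2) # shape 4, scale 1
gamma_from_moments <- function(mean, sd) {
  assert_nonneg(sd, "sd")
  if (!is.finite(mean) || mean < 0 || (mean == 0 && sd > 0))
    stop_config("gamma undefined for mean = %s with sd = %s", mean, sd)
  degenerate <- sd == 0 || mean == 0
  structure(list(
    shape = if (degenerate) NA_real_ else mean^2 / sd^2,
    scale = if (degenerate) NA_real_ else sd^2 / mean,
    mean = mean, sd = sd, degenerate = degenerate
  ), class = "gamma_params")
}

draw_gamma_params <- function(params, n) {
  if (params$degenerate) rep(params$mean, n)
  else stats::rgamma(n, shape = params$shape, scale = params$scale)
}

#' Probabilistic sensitivity analysis of a perinatal Markov model
#'
#' Each iteration draws every state's per-cycle cost from a gamma
#' distribution parameterised by the state's sample mean and standard
#' deviation (independently across states), and accumulates the cycle-
#' weighted total. The reported 90% uncertainty interval is the empirical
#' 5th-95th percentile range of the iterated totals.
#'
#' @param spec A populated `markov_spec`.
#' @param n_iterations Number of PSA iterations (default 10000).
#' @param seed Integer seed for the model's random stream.
#' @param keep_draws Keep the per-iteration totals (needed to combine
#'   mother and child uncertainty intervals).
#' @return An object of class `psa_result`: `deterministic_total`,
#'   `psa_mean`, `ui_lower`, `ui_upper`, `n_iterations`, `seed`, and the
#'   model coordinates; `draws` when `keep_draws = TRUE`.
#' @export
run_psa <- function(spec, n_iterations = 10000L, seed = 1L, keep_draws = FALSE) {
  assert_count(n_iterations, "n_iterations", min = 1L)
  det <- deterministic_total(spec)
  set.seed(seed)
  totals <- numeric(n_iterations)
  for (i in seq_len(nrow(spec$states))) {
    gp <- gamma_from_moments(spec$states$cost_mean[i], spec$states$cost_sd[i])
    totals <- totals + draw_gamma_params(gp, n_iterations) * spec$states$n_cycles[i]
  }
  q <- unname(stats::quantile(totals, c(0.05, 0.95)))
  structure(list(
    deterministic_total = det,
    psa_mean = mean(totals),
    ui_lower = q[1], ui_upper = q[2],
    n_iterations = n_iterations, seed = seed,
    group = spec$group, perspective = spec$perspective, person = spec$person,
    draws = if (keep_draws) totals else NULL
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA (%s / %s / %s): deterministic %.2f; mean %.2f [90%% UI %.2f-%.2f] over %d iterations\n",
              x$group %||% "?", x$perspective %||% "?", x$person %||% "?",
              x$deterministic_total, x$psa_mean, x$ui_lower, x$ui_upper,
              x$n_iterations))
  invisible(x)
}
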