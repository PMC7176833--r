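#' Configuration for a full pipeline run
#'
#' @param cohort A [cohort_config()] for synthetic generation, or a path to a
#'   cohort CSV in the [write_cohort()] schema.
#' @param finance Provider finance table (data frame or CSV path); defaults
#'   to the bundled synthetic provincial table.
#' @param n_iterations PSA iterations per model.
#' @param seed Master seed; per-model PSA streams are derived from it.
#' @param hrsd_cutoff Depression cutoff on the HRSD.
#' @param catastrophic_threshold Share of per-capita income above which
#'   care-seeking spending is flagged catastrophic.
#' @param working_days_per_year,working_hours_per_day Opportunity-cost
#'   valuation constants.
#' @param currency Reporting currency, `"USD"` or `"ZAR"`; all internal
#'   arithmetic is in ZAR at 2014/15 prices and conversion happens once at
#'   reporting.
#' @param zar_per_usd Exchange rate for USD reporting.
#' @param out_dir Output directory for tables and manifests; `NULL` returns
#'   the bundle without writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       finance = synthetic_finance_table(),
                       n_iterations = 10000L,
                       seed = 20140115L,
                       hrsd_cutoff = 8L,
                       catastrophic_threshold = 0.10,
                       working_days_per_year = 228L,
                       working_hours_per_day = 8,
                       currency = c("USD", "ZAR"),
                       zar_per_usd = 11.69,
                       out_dir = NULL) {
  currency <- match.arg(currency)
  assert_count(n_iterations, "n_iterations", min = 1L)
  assert_count(seed, "seed")
  assert_prob(catastrophic_threshold, "catastrophic_threshold")
  assert_pos(zar_per_usd, "zar_per_usd")
  if (is.character(cohort) && !file.exists(cohort))
    stop_config("configuration error: cohort CSV '%s' does not exist", cohort)
  if (is.character(finance) && !file.exists(finance))
    stop_config("configuration error: finance CSV '%s' does not exist", finance)
  structure(list(cohort = cohort, finance = finance,
                 n_iterations = n_iterations, seed = seed,
                 hrsd_cutoff = hrsd_cutoff,
                 catastrophic_threshold = catastrophic_threshold,
                 working_days_per_year = working_days_per_year,
                 working_hours_per_day = working_hours_per_day,
                 currency = currency, zar_per_usd = zar_per_usd,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar settings map directly onto [run_config()] arguments; `cohort` and
#' `finance` entries that are strings are treated as CSV paths.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

#' Combine mother and child model results into a dyad total
#'
#' Total mean cost is the sum of the mother and child mean costs. When both
#' arguments are [run_psa()] results carrying their per-iteration draws, the
#' combined 90% uncertainty interval is recomputed from the per-iteration
#' sums of the two models' draws (interval endpoints are not additive).
#' Plain numeric means are summed directly.
#'
#' @param mother,child `psa_result` objects for the same group and
#'   perspective, or numeric mean costs.
#' @return For numeric input, the summed mean. For `psa_result` input, a
#'   `psa_result` for the mother-child dyad.
#' @export
#' @examples
#' combine_mother_child(372, 433) # 805
combine_mother_child <- function(mother, child) {
  if (is.numeric(mother) && is.numeric(child)) {
    assert_nonneg(mother, "mother")
    assert_nonneg(child, "child")
    return(mother + child)
  }
  if (!inherits(mother, "psa_result") || !inherits(child, "psa_result"))
    stop_config("combine_mother_child needs two psa_result objects or two numbers")
  if (!identical(mother$group, child$group) ||
      !identical(mother$perspective, child$perspective))
    stop_config("mismatched models: %s/%s vs %s/%s", mother$group,
                mother$perspective, child$group, child$perspective)
  if (!identical(mother$person, "mother") || !identical(child$person, "child"))
    stop_config("arguments must be the mother and child models, in that order")
  draws <- if (!is.null(mother$draws) && !is.null(child$draws) &&
               length(mother$draws) == length(child$draws)) {
    mother$draws + child$draws
  } else NULL
  q <- if (!is.null(draws)) unname(stats::quantile(draws, c(0.05, 0.95))) else c(NA_real_, NA_real_)
  structure(list(
    deterministic_total = mother$deterministic_total + child$deterministic_total,
    psa_mean = mother$psa_mean + child$psa_mean,
    ui_lower = q[1], ui_upper = q[2],
    n_iterations = mother$n_iterations, seed = mother$seed,
    group = mother$group, perspective = mother$perspective,
    person = "mother_child", draws = draws
  ), class = "psa_result")
}

# wave-level socioeconomic outcomes: MCA wealth score, SES group, imputed and
# per-capita income
asset_columns <- function() {
  c("dwelling_formal", "owns_dwelling", "electricity", "piped_water",
    "income_source_fixed", "bank_account", "food_shop_supermarket", "education")
}

socioeconomic_outcomes <- function(records, income_bounds, hrsd_cutoff = 8L) {
  out <- vector("list", 4L)
  for (w in sort(unique(records$wave))) {
    rows <- records[records$wave == w, , drop = FALSE]
    mca <- mca_scores(rows[, asset_columns()])
    ses <- assign_ses_groups(mca$scores, 2L, ids = rows$participant_id)
    imp <- impute_household_income(rows$income_category, rows$employed,
                                   rows$education, mca$scores, income_bounds)
    out[[w]] <- data.frame(
      participant_id = rows$participant_id,
      wave = w,
      depressed = assign_depression_status(rows$hrsd_score, hrsd_cutoff),
      wealth_score = mca$scores,
      ses_group = as.character(ses),
      household_income = imp$income,
      per_capita_income = per_capita_income(imp$income, rows$household_size),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

patient_cost_breakdown <- function(records, rate) {
  per_visit_hours <- (records$travel_minutes + records$wait_minutes +
                        records$consult_minutes) / 60
  data.frame(
    participant_id = records$participant_id,
    wave = records$wave,
    mother_time = rate * (records$clinic_visits_3m + records$opd_visits_3m) * per_visit_hours,
    mother_travel = records$travel_cost_zar,
    mother_fees = records$user_fees_zar,
    child_time = rate * (records$child_clinic_visits_3m + records$child_opd_visits_3m) * per_visit_hours,
    child_travel = records$child_travel_cost_zar,
    child_fees = records$child_user_fees_zar,
    stringsAsFactors = FALSE
  )
}

characteristics_comparisons <- function(records, outcomes, hrsd_cutoff = 8L) {
  tests <- list()
  add <- function(x) tests[[length(tests) + 1L]] <<- x
  for (w in sort(unique(records$wave))) {
    rows <- records[records$wave == w, , drop = FALSE]
    oc <- outcomes[outcomes$wave == w, , drop = FALSE]
    d <- assign_depression_status(rows$hrsd_score, hrsd_cutoff)
    if (length(unique(d[!is.na(d)])) < 2L) next
    grp <- ifelse(d, "depressed", "non_depressed")

    chi_row <- function(variable, values) {
      tab <- table(grp, values)
      if (ncol(tab) < 2L) return(NULL)
      cmp <- pearson_chi2(tab)
      data.frame(wave = w, variable = variable, test = cmp$test_name,
                 statistic = cmp$statistic, p_value = cmp$p_value,
                 stringsAsFactors = FALSE)
    }
    kw_row <- function(variable, values) {
      cmp <- kruskal_wallis(split(values, grp))
      data.frame(wave = w, variable = variable, test = cmp$test_name,
                 statistic = cmp$statistic, p_value = cmp$p_value,
                 stringsAsFactors = FALSE)
    }
    add(chi_row("employed", rows$employed))
    add(chi_row("has_partner", rows$has_partner))
    add(chi_row("ses_group", oc$ses_group[match(rows$participant_id, oc$participant_id)]))
    add(kw_row("per_capita_income",
               oc$per_capita_income[match(rows$participant_id, oc$participant_id)]))
  }
  do.call(rbind, Filter(Negate(is.null), tests))
}

#' Run the full cost-of-illness pipeline
#'
#' Executes every stage end-to-end: cohort generation (or loading), provider
#' unit costing, socioeconomic outcome construction, patient costing, the
#' eight perinatal Markov models (group x perspective x person) with gamma
#' PSA, mother-child dyad totals, and the report tables. All internal
#' arithmetic is in ZAR at 2014/15 prices; costs are converted once to the
#' reporting currency.
#'
#' @param config A [run_config()].
#' @return Invisibly, a `report_bundle` list: `cohort`, `unit_costs`,
#'   `valuation`, `outcomes`, `patient_costs`, `characteristics`,
#'   `psa_results` (8 models), `dyad_totals`, `provider_cost_table`,
#'   `patient_cost_table`, `income_shares`, `manifest`. Written to
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_config("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  usd <- function(x) if (config$currency == "USD") convert_currency(x, config$zar_per_usd) else x

  cohort <- stage("synthetic_cohort", {
    if (is.character(config$cohort)) read_cohort(config$cohort)
    else generate_cohort(config$cohort)
  })
  records <- cohort$records

  unit_costs <- stage("unit_costing", build_unit_cost_table(
    config$finance, zar_per_usd = config$zar_per_usd))

  income_bounds <- if (inherits(config$cohort, "cohort_config")) {
    config$cohort$income_category_bounds
  } else {
    cohort_config()$income_category_bounds
  }

  outcomes <- stage("socioeconomic",
                    socioeconomic_outcomes(records, income_bounds, config$hrsd_cutoff))

  valuation <- stage("patient_costing", {
    base <- outcomes[outcomes$wave == 1L, ]
    time_valuation(mean(base$per_capita_income),
                   config$working_days_per_year, config$working_hours_per_day)
  })
  rate <- hourly_opportunity_rate(valuation)

  patient_costs <- stage("patient_costing", patient_cost_breakdown(records, rate))
  patient_costs$total <- rowSums(patient_costs[, c("mother_time", "mother_travel",
                                                   "mother_fees", "child_time",
                                                   "child_travel", "child_fees")])

  income_shares <- stage("patient_costing", {
    oc <- outcomes[match(paste(patient_costs$participant_id, patient_costs$wave),
                         paste(outcomes$participant_id, outcomes$wave)), ]
    ok <- oc$per_capita_income > 0
    share <- cost_income_share(patient_costs$total[ok],
                               oc$per_capita_income[ok] * 3,
                               config$catastrophic_threshold)
    df <- data.frame(participant_id = patient_costs$participant_id[ok],
                     wave = patient_costs$wave[ok],
                     depressed = oc$depressed[ok],
                     share = share$share,
                     catastrophic = share$catastrophic,
                     stringsAsFactors = FALSE)
    agg <- stats::aggregate(cbind(share, catastrophic) ~ depressed, df, mean)
    list(by_participant = df, by_group = agg,
         n_excluded_nonpositive_income = sum(!ok))
  })

  characteristics <- stage("socioeconomic",
                           characteristics_comparisons(records, outcomes, config$hrsd_cutoff))

  aug <- augment_spread_totals(records)
  model_grid <- expand.grid(group = c("depressed", "non_depressed"),
                            perspective = c("provider", "patient"),
                            person = c("mother", "child"),
                            stringsAsFactors = FALSE)
  psa_results <- stage("markov_engine", {
    res <- vector("list", nrow(model_grid))
    for (i in seq_len(nrow(model_grid))) {
      g <- model_grid$group[i]; pv <- model_grid$perspective[i]; pr <- model_grid$person[i]
      spec <- build_perinatal_spec(g, pv, pr)
      spec <- populate_markov_spec(spec, aug, unit_costs,
                                   rate = if (pv == "patient") rate else 0,
                                   hrsd_cutoff = config$hrsd_cutoff)
      res[[i]] <- run_psa(spec, config$n_iterations,
                          seed = config$seed + i, keep_draws = TRUE)
    }
    names(res) <- sprintf("%s.%s.%s", model_grid$group, model_grid$perspective,
                          model_grid$person)
    res
  })

  dyad_totals <- stage("reporting", {
    combos <- expand.grid(group = c("depressed", "non_depressed"),
                          perspective = c("provider", "patient"),
                          stringsAsFactors = FALSE)
    out <- vector("list", nrow(combos))
    for (i in seq_len(nrow(combos))) {
      g <- combos$group[i]; pv <- combos$perspective[i]
      out[[i]] <- combine_mother_child(
        psa_results[[sprintf("%s.%s.mother", g, pv)]],
        psa_results[[sprintf("%s.%s.child", g, pv)]]
      )
    }
    names(out) <- sprintf("%s.%s", combos$group, combos$perspective)
    out
  })

  cost_row <- function(r) data.frame(
    group = r$group, perspective = r$perspective, person = r$person,
    mean_cost = usd(r$psa_mean), deterministic = usd(r$deterministic_total),
    ui_lower = usd(r$ui_lower), ui_upper = usd(r$ui_upper),
    stringsAsFactors = FALSE
  )
  all_rows <- do.call(rbind, lapply(c(psa_results, dyad_totals), cost_row))
  rownames(all_rows) <- NULL
  provider_cost_table <- stage("reporting", {
    tab <- all_rows[all_rows$perspective == "provider", ]
    comp <- component_totals(aug, unit_costs, rate, config$hrsd_cutoff, "provider")
    list(totals = tab, components = data.frame(
      comp[, c("group", "person", "component")],
      total_cost = usd(comp$total_cost), stringsAsFactors = FALSE))
  })
  patient_cost_table <- stage("reporting", {
    tab <- all_rows[all_rows$perspective == "patient", ]
    comp <- component_totals(aug, unit_costs, rate, config$hrsd_cutoff, "patient")
    list(totals = tab, components = data.frame(
      comp[, c("group", "person", "component")],
      total_cost = usd(comp$total_cost), stringsAsFactors = FALSE))
  })

  manifest <- stage("reporting", {
    cfg_json <- jsonlite::serializeJSON(config[setdiff(names(config), "out_dir")])
    tf <- tempfile(); writeLines(cfg_json, tf)
    hash <- unname(tools::md5sum(tf)); unlink(tf)
    list(package_version = as.character(utils::packageVersion("pericost")),
         seed = config$seed, n_iterations = config$n_iterations,
         currency = config$currency, zar_per_usd = config$zar_per_usd,
         hourly_rate_zar = rate, config_hash = hash,
         flow = cohort$flow, cohort_log = cohort$log)
  })

  bundle <- structure(list(
    cohort = cohort, unit_costs = unit_costs, valuation = valuation,
    outcomes = outcomes, patient_costs = patient_costs,
    characteristics = characteristics, psa_results = psa_results,
    dyad_totals = dyad_totals, provider_cost_table = provider_cost_table,
    patient_cost_table = patient_cost_table, income_shares = income_shares,
    manifest = manifest, config = config
  ), class = "report_bundle")

  if (!is.null(config$out_dir)) stage("reporting", write_bundle(bundle, config$out_dir))
  invisible(bundle)
}

# horizon totals of each cost component (component per-cycle mean x cycles,
# summed over states) by group and person
component_totals <- function(aug, unit_costs, rate, hrsd_cutoff, perspective) {
  states <- perinatal_states()
  rows <- list()
  for (g in c("depressed", "non_depressed")) {
    for (pr in c("mother", "child")) {
      acc <- NULL
      for (i in seq_len(nrow(states))) {
        cc <- state_cycle_costs(aug, states$name[i], g, perspective, pr,
                                unit_costs, rate, hrsd_cutoff)
        comp <- setdiff(names(cc), c("participant_id", "cost"))
        means <- vapply(cc[comp], mean, numeric(1)) * states$n_cycles[i]
        acc <- if (is.null(acc)) means else acc + means
      }
      rows[[paste(g, pr)]] <- data.frame(group = g, person = pr,
                                         component = names(acc),
                                         total_cost = unname(acc),
                                         stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

psa_result_record <- function(r) {
  list(group = r$group, perspective = r$perspective, person = r$person,
       deterministic_total = r$deterministic_total, psa_mean = r$psa_mean,
       ui_lower = r$ui_lower, ui_upper = r$ui_upper,
       n_iterations = r$n_iterations, seed = r$seed)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(bundle$cohort, dir)
  jsonlite::write_json(unclass(bundle$unit_costs),
                       file.path(dir, "unit_costs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(bundle$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  utils::write.csv(bundle$patient_costs, file.path(dir, "patient_costs.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$characteristics, file.path(dir, "characteristics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(bundle$psa_results, psa_result_record),
                       file.path(dir, "psa_results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(lapply(bundle$dyad_totals, psa_result_record),
                       file.path(dir, "dyad_totals.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(bundle$provider_cost_table$totals,
                   file.path(dir, "provider_costs.csv"), row.names = FALSE)
  utils::write.csv(bundle$provider_cost_table$components,
                   file.path(dir, "provider_cost_components.csv"), row.names = FALSE)
  utils::write.csv(bundle$patient_cost_table$totals,
                   file.path(dir, "patient_cost_totals.csv"), row.names = FALSE)
  utils::write.csv(bundle$patient_cost_table$components,
                   file.path(dir, "patient_cost_components.csv"), row.names = FALSE)
  utils::write.csv(bundle$income_shares$by_group,
                   file.path(dir, "income_shares.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Perinatal cost-of-illness report bundle\n")
  cat(sprintf("  cohort: %d participants retained\n", x$cohort$flow$retained))
  cat(sprintf("  currency: %s\n", x$config$currency))
  cat("  dyad totals (mother + child, PSA mean [90% UI]):\n")
  usd <- function(v) if (x$config$currency == "USD")
    convert_currency(v, x$config$zar_per_usd) else v
  for (nm in names(x$dyad_totals)) {
    r <- x$dyad_totals[[nm]]
    cat(sprintf("    %-28s %8.0f [%7.0f-%8.0f]\n", nm, usd(r$psa_mean),
                usd(r$ui_lower), usd(r$ui_upper)))
  }
  invisible(x)
}
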