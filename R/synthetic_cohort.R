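#' Configuration for the synthetic perinatal cohort generator
#'
#' Builds the full parameter set for [generate_cohort()]. Defaults emulate a
#' peri-urban South African antenatal cohort followed over four interview
#' waves (baseline in the second trimester, 8 months gestation, 3 and 12
#' months postpartum): 2192 women screened, 425 screen-positive and enrolled,
#' 6 excluded post-enrolment, 419 retained; nearly all participants above the
#' depression cutoff at baseline with substantial non-depressed fractions at
#' later waves; overdispersed utilisation counts with higher inpatient use and
#' more hospital deliveries in the depressed group; and monotone wave-on-wave
#' attrition.
#'
#' Utilisation counts are drawn negative-binomial (mean/dispersion); times and
#' out-of-pocket amounts are drawn gamma (mean/shape). Every distribution
#' takes a pair of means named `depressed` / `non_depressed`.
#'
#' @param n_screened Number of women screened at the first antenatal visit.
#' @param n_screen_positive Number screening positive and enrolled.
#' @param n_excluded Number excluded after enrolment.
#' @param attrition_rate_per_wave Per-wave probability that a participant
#'   present at wave w is lost before wave w+1 (monotone dropout).
#' @param depression_prevalence_by_wave Length-4 vector of probabilities that
#'   a participant present at each wave scores above the depression cutoff.
#' @param hrsd_cutoff Depression cutoff on the Hamilton Rating Scale for
#'   Depression; scores strictly greater are classed depressed.
#' @param utilisation Named list of per-service negative-binomial parameters,
#'   each `list(mean = c(depressed=, non_depressed=), dispersion=)`.
#' @param delivery_hospital_prob Probability of a hospital (vs midwife
#'   obstetric unit) delivery, by group.
#' @param delivery_extra_days_mean Mean extra facility days beyond the first,
#'   by delivery site (`mou`, `hospital`); extra days are Poisson.
#' @param time_money Named list of gamma parameters for per-visit minutes and
#'   per-window money amounts, each `list(mean = c(depressed=,
#'   non_depressed=), shape=)`.
#' @param income_category_bounds List of `c(lower, upper)` monthly household
#'   income bands in ZAR; the top band may be right-open (`Inf`).
#' @param income_category_probs 2 x K matrix of category probabilities, rows
#'   `depressed` and `non_depressed`.
#' @param household_size_lambda Household size is `1 + Poisson(lambda)`.
#' @param employment_prob Employment probability by group (applied per wave).
#' @param partner_prob_by_wave Length-4 partner-status probabilities.
#' @param wealth_shift_depressed Downward shift of the latent wealth score for
#'   participants depressed at a wave (drives asset indicators).
#' @param depression_autocorrelation Probability that a participant's status
#'   simply carries over from the previous wave instead of being redrawn;
#'   0 (the default) redraws status independently at every wave.
#' @param random_seed Integer seed; a fixed seed makes output bit-identical.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_screened = 2192L,
                          n_screen_positive = 425L,
                          n_excluded = 6L,
                          attrition_rate_per_wave = 0.04,
                          depression_prevalence_by_wave = c(403 / 419, 0.72, 0.62, 0.55),
                          hrsd_cutoff = 8L,
                          utilisation = list(
                            clinic_visits_3m        = list(mean = c(depressed = 1.6,  non_depressed = 1.4),  dispersion = 1.2),
                            opd_visits_3m           = list(mean = c(depressed = 0.6,  non_depressed = 0.35), dispersion = 0.8),
                            inpatient_days_6m       = list(mean = c(depressed = 0.9,  non_depressed = 0.35), dispersion = 0.5),
                            antenatal_visits_total  = list(mean = c(depressed = 5,    non_depressed = 5),    dispersion = 4),
                            wellbaby_visits_total   = list(mean = c(depressed = 6,    non_depressed = 6),    dispersion = 4),
                            child_clinic_visits_3m  = list(mean = c(depressed = 1.7,  non_depressed = 1.5),  dispersion = 1.2),
                            child_opd_visits_3m     = list(mean = c(depressed = 0.5,  non_depressed = 0.3),  dispersion = 0.8),
                            child_inpatient_days_6m = list(mean = c(depressed = 0.8,  non_depressed = 0.3),  dispersion = 0.5)
                          ),
                          delivery_hospital_prob = c(depressed = 0.45, non_depressed = 0.25),
                          delivery_extra_days_mean = c(mou = 0.2, hospital = 1.5),
                          time_money = list(
                            travel_minutes        = list(mean = c(depressed = 35, non_depressed = 30), shape = 2),
                            wait_minutes          = list(mean = c(depressed = 100, non_depressed = 90), shape = 2),
                            consult_minutes       = list(mean = c(depressed = 15, non_depressed = 15), shape = 3),
                            travel_cost_zar       = list(mean = c(depressed = 25, non_depressed = 20), shape = 1.5),
                            user_fees_zar         = list(mean = c(depressed = 12, non_depressed = 8),  shape = 1),
                            child_travel_cost_zar = list(mean = c(depressed = 20, non_depressed = 16), shape = 1.5),
                            child_user_fees_zar   = list(mean = c(depressed = 8,  non_depressed = 5),  shape = 1)
                          ),
                          income_category_bounds = list(
                            c(0, 1000), c(1000, 2000), c(2000, 3500), c(3500, 6000), c(6000, Inf)
                          ),
                          income_category_probs = rbind(
                            depressed     = c(0.28, 0.32, 0.22, 0.12, 0.06),
                            non_depressed = c(0.20, 0.28, 0.25, 0.17, 0.10)
                          ),
                          household_size_lambda = 3,
                          employment_prob = c(depressed = 0.45, non_depressed = 0.60),
                          partner_prob_by_wave = c(0.75, 0.70, 0.63, 0.57),
                          wealth_shift_depressed = 0.5,
                          depression_autocorrelation = 0,
                          random_seed = 1L) {
  config <- list(
    n_screened = n_screened,
    n_screen_positive = n_screen_positive,
    n_excluded = n_excluded,
    attrition_rate_per_wave = attrition_rate_per_wave,
    depression_prevalence_by_wave = depression_prevalence_by_wave,
    hrsd_cutoff = hrsd_cutoff,
    utilisation = utilisation,
    delivery_hospital_prob = delivery_hospital_prob,
    delivery_extra_days_mean = delivery_extra_days_mean,
    time_money = time_money,
    income_category_bounds = income_category_bounds,
    income_category_probs = income_category_probs,
    household_size_lambda = household_size_lambda,
    employment_prob = employment_prob,
    partner_prob_by_wave = partner_prob_by_wave,
    wealth_shift_depressed = wealth_shift_depressed,
    depression_autocorrelation = depression_autocorrelation,
    random_seed = random_seed
  )
  class(config) <- "cohort_config"
  validate_cohort_config(config)
  config
}

#' Validate a cohort configuration
#'
#' @param config A `cohort_config` list.
#' @return The config, invisibly, if valid; otherwise an error.
#' @export
validate_cohort_config <- function(config) {
  assert_count(config$n_screened, "n_screened", min = 1L)
  assert_count(config$n_screen_positive, "n_screen_positive")
  assert_count(config$n_excluded, "n_excluded")
  if (config$n_screen_positive > config$n_screened)
    stop_config("configuration error: screen positives (%d) exceed screened (%d)",
                config$n_screen_positive, config$n_screened)
  if (config$n_excluded > config$n_screen_positive)
    stop_config("configuration error: exclusions (%d) exceed enrolment (%d)",
                config$n_excluded, config$n_screen_positive)
  assert_prob(config$attrition_rate_per_wave, "attrition_rate_per_wave")
  if (length(config$depression_prevalence_by_wave) != 4L)
    stop_config("configuration error: depression_prevalence_by_wave must have length 4")
  assert_prob(config$depression_prevalence_by_wave, "depression_prevalence_by_wave")
  assert_count(config$hrsd_cutoff, "hrsd_cutoff")
  for (nm in names(config$utilisation)) {
    pars <- config$utilisation[[nm]]
    assert_nonneg(pars$mean, paste0("utilisation$", nm, "$mean"))
    assert_pos(pars$dispersion, paste0("utilisation$", nm, "$dispersion"))
  }
  assert_prob(config$delivery_hospital_prob, "delivery_hospital_prob")
  assert_nonneg(config$delivery_extra_days_mean, "delivery_extra_days_mean")
  for (nm in names(config$time_money)) {
    pars <- config$time_money[[nm]]
    assert_nonneg(pars$mean, paste0("time_money$", nm, "$mean"))
    assert_pos(pars$shape, paste0("time_money$", nm, "$shape"))
  }
  k <- length(config$income_category_bounds)
  if (k < 1L || !all(vapply(config$income_category_bounds, length, 1L) == 2L))
    stop_config("configuration error: income_category_bounds must be a list of c(lower, upper)")
  probs <- config$income_category_probs
  if (!is.matrix(probs) || nrow(probs) != 2L || ncol(probs) != k)
    stop_config("configuration error: income_category_probs must be a 2 x %d matrix", k)
  assert_prob(probs, "income_category_probs")
  if (any(abs(rowSums(probs) - 1) > 1e-8))
    stop_config("configuration error: income_category_probs rows must sum to 1")
  assert_nonneg(config$household_size_lambda, "household_size_lambda")
  assert_prob(config$employment_prob, "employment_prob")
  if (length(config$partner_prob_by_wave) != 4L)
    stop_config("configuration error: partner_prob_by_wave must have length 4")
  assert_prob(config$partner_prob_by_wave, "partner_prob_by_wave")
  assert_prob(config$depression_autocorrelation, "depression_autocorrelation")
  assert_count(config$random_seed, "random_seed")
  invisible(config)
}

#' Classify depression status from an HRSD score
#'
#' Status is depressed when the Hamilton Rating Scale for Depression score is
#' strictly greater than the cutoff (default 8). Missing scores return `NA`
#' ("unknown"); such records are excluded from group summaries downstream and
#' the exclusion is counted in the run log.
#'
#' @param hrsd_score Numeric vector of non-negative HRSD scores (NA allowed).
#' @param cutoff Cutoff score; strictly greater means depressed.
#' @return Logical vector, `NA` where the score is missing.
#' @export
#' @examples
#' assign_depression_status(c(9, 8, 0, NA))
assign_depression_status <- function(hrsd_score, cutoff = 8L) {
  if (any(hrsd_score < 0, na.rm = TRUE))
    stop_config("validation error: hrsd_score must be >= 0")
  hrsd_score > cutoff
}

draw_by_group <- function(depressed, pars, what = c("nbinom", "gamma")) {
  what <- match.arg(what)
  n <- length(depressed)
  mu <- ifelse(depressed, pars$mean[["depressed"]], pars$mean[["non_depressed"]])
  if (what == "nbinom") {
    stats::rnbinom(n, size = pars$dispersion, mu = mu)
  } else {
    rgamma_mean(n, mu, pars$shape)
  }
}

#' Generate a synthetic perinatal cohort
#'
#' Simulates the full screening flow and participant-by-wave interview
#' records: depression status at each wave, socioeconomic and asset
#' indicators, health-service utilisation for the mother and her child(ren),
#' per-visit travel/wait/consultation times and per-window travel costs and
#' user fees. Attrition is monotone: a participant absent at wave w is absent
#' at all later waves.
#'
#' Wave-specific fields follow the interview instruments: total antenatal
#' visits are asked only at wave 2 (8 months gestation), delivery site and
#' facility days only at wave 3 (3 months postpartum), and total well-baby
#' visits only at wave 4 (12 months postpartum); they are `NA` elsewhere.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `perinatal_cohort`: a list with `records` (one
#'   data.frame row per participant x wave attended), `flow` (screening-flow
#'   counts: screened, screen_positive, enrolled, excluded, retained), and
#'   `log` (character vector of warnings such as empty group x wave cells).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(random_seed = 7))
#' cohort$flow$retained
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$random_seed)

  flow <- list(
    screened = as.integer(config$n_screened),
    screen_positive = as.integer(config$n_screen_positive),
    enrolled = as.integer(config$n_screen_positive),
    excluded = as.integer(config$n_excluded),
    retained = as.integer(config$n_screen_positive - config$n_excluded)
  )
  n <- flow$retained
  if (n < 1L) stop_config("configuration error: no participants retained")
  log <- character()

  ids <- sprintf("P%05d", seq_len(n))

  # participant-level (time-invariant) characteristics
  household_size <- 1L + stats::rpois(n, config$household_size_lambda)
  base_wealth <- stats::rnorm(n)
  education <- cut(base_wealth + stats::rnorm(n, sd = 0.8),
                   breaks = c(-Inf, -0.6, 0.7, Inf),
                   labels = c("primary", "some_secondary", "matric_plus"))
  education <- as.character(education)

  # monotone attrition
  present <- matrix(FALSE, n, 4)
  present[, 1] <- TRUE
  for (w in 2:4) {
    present[, w] <- present[, w - 1] & (stats::runif(n) >= config$attrition_rate_per_wave)
  }

  # per-wave depression status, optionally sticky
  depressed <- matrix(NA, n, 4)
  depressed[, 1] <- stats::runif(n) < config$depression_prevalence_by_wave[1]
  for (w in 2:4) {
    carry <- stats::runif(n) < config$depression_autocorrelation
    fresh <- stats::runif(n) < config$depression_prevalence_by_wave[w]
    depressed[, w] <- ifelse(carry, depressed[, w - 1], fresh)
  }

  waves <- vector("list", 4)
  cat_labels <- income_category_labels(config$income_category_bounds)
  for (w in 1:4) {
    idx <- which(present[, w])
    nw <- length(idx)
    d <- depressed[idx, w]
    for (g in c(TRUE, FALSE)) {
      if (!any(d == g)) {
        log <- c(log, sprintf("empty %s cell at wave %d",
                              if (g) "depressed" else "non-depressed", w))
      }
    }

    hrsd <- integer(nw)
    ndep <- sum(d)
    hrsd[d] <- config$hrsd_cutoff + 1L + stats::rpois(ndep, 5)
    hrsd[!d] <- stats::rbinom(nw - ndep, config$hrsd_cutoff, 0.45)

    # asset indicators driven by a latent wealth score, shifted down when
    # depressed at this wave
    z <- base_wealth[idx] - ifelse(d, config$wealth_shift_depressed, 0)
    bern <- function(shift) stats::runif(nw) < stats::plogis(z + shift)
    electricity <- bern(0.9)
    piped_water <- bern(0.6)
    dwelling_formal <- bern(0.2)
    owns_dwelling <- bern(0)
    income_source_fixed <- bern(-0.2)
    bank_account <- bern(0.4)
    food_shop_supermarket <- bern(0.3)

    probs <- config$income_category_probs
    income_category <- character(nw)
    if (ndep > 0)
      income_category[d] <- sample(cat_labels, ndep, TRUE, probs["depressed", ])
    if (nw - ndep > 0)
      income_category[!d] <- sample(cat_labels, nw - ndep, TRUE, probs["non_depressed", ])

    employed <- stats::runif(nw) <
      ifelse(d, config$employment_prob[["depressed"]], config$employment_prob[["non_depressed"]])
    has_partner <- stats::runif(nw) < config$partner_prob_by_wave[w]

    u <- config$utilisation
    rec <- data.frame(
      participant_id = ids[idx],
      wave = w,
      hrsd_score = hrsd,
      employed = employed,
      has_partner = has_partner,
      income_category = income_category,
      household_size = household_size[idx],
      dwelling_formal = dwelling_formal,
      owns_dwelling = owns_dwelling,
      electricity = electricity,
      piped_water = piped_water,
      income_source_fixed = income_source_fixed,
      bank_account = bank_account,
      food_shop_supermarket = food_shop_supermarket,
      education = education[idx],
      clinic_visits_3m = draw_by_group(d, u$clinic_visits_3m),
      opd_visits_3m = draw_by_group(d, u$opd_visits_3m),
      inpatient_days_6m = draw_by_group(d, u$inpatient_days_6m),
      antenatal_visits_total = NA_integer_,
      delivery_site = NA_character_,
      delivery_days = NA_integer_,
      wellbaby_visits_total = NA_integer_,
      child_clinic_visits_3m = draw_by_group(d, u$child_clinic_visits_3m),
      child_opd_visits_3m = draw_by_group(d, u$child_opd_visits_3m),
      child_inpatient_days_6m = draw_by_group(d, u$child_inpatient_days_6m),
      travel_minutes = draw_by_group(d, config$time_money$travel_minutes, "gamma"),
      wait_minutes = draw_by_group(d, config$time_money$wait_minutes, "gamma"),
      consult_minutes = draw_by_group(d, config$time_money$consult_minutes, "gamma"),
      travel_cost_zar = draw_by_group(d, config$time_money$travel_cost_zar, "gamma"),
      user_fees_zar = draw_by_group(d, config$time_money$user_fees_zar, "gamma"),
      child_travel_cost_zar = draw_by_group(d, config$time_money$child_travel_cost_zar, "gamma"),
      child_user_fees_zar = draw_by_group(d, config$time_money$child_user_fees_zar, "gamma"),
      stringsAsFactors = FALSE
    )

    if (w == 2L) {
      rec$antenatal_visits_total <- draw_by_group(d, u$antenatal_visits_total)
    }
    if (w == 3L) {
      p_hosp <- ifelse(d, config$delivery_hospital_prob[["depressed"]],
                       config$delivery_hospital_prob[["non_depressed"]])
      site <- ifelse(stats::runif(nw) < p_hosp, "hospital", "MOU")
      extra <- config$delivery_extra_days_mean[ifelse(site == "hospital", "hospital", "mou")]
      rec$delivery_site <- site
      rec$delivery_days <- 1L + stats::rpois(nw, extra)
    }
    if (w == 4L) {
      rec$wellbaby_visits_total <- draw_by_group(d, u$wellbaby_visits_total)
    }
    waves[[w]] <- rec
  }

  records <- do.call(rbind, waves)
  records <- records[order(records$participant_id, records$wave), ]
  rownames(records) <- NULL

  structure(list(records = records, flow = flow, log = log,
                 config = config),
            class = "perinatal_cohort")
}

income_category_labels <- function(bounds) {
  vapply(bounds, function(b) {
    if (is.infinite(b[2])) sprintf("%g+", b[1]) else sprintf("%g-%g", b[1], b[2])
  }, character(1))
}

#' @export
print.perinatal_cohort <- function(x, ...) {
  cat("Synthetic perinatal cohort\n")
  cat(sprintf("  screened %d, screen-positive %d, excluded %d, retained %d\n",
              x$flow$screened, x$flow$screen_positive, x$flow$excluded, x$flow$retained))
  tab <- table(x$records$wave)
  cat("  participants per wave:", paste(tab, collapse = ", "), "\n")
  if (length(x$log)) cat("  log:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}

#' Write cohort records and screening-flow summary to disk
#'
#' @param cohort A `perinatal_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (cohort CSV and flow JSON).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "cohort.csv")
  json <- file.path(dir, "flow.json")
  utils::write.csv(cohort$records, csv, row.names = FALSE)
  jsonlite::write_json(cohort$flow, json, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(cohort = csv, flow = json))
}

#' Read a cohort table from CSV
#'
#' Expects the column schema written by [write_cohort()].
#'
#' @param path CSV path.
#' @return A `perinatal_cohort` with flow counts reconstructed from the data
#'   where possible (screened/enrolled unknown for external data).
#' @export
read_cohort <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "wave", "hrsd_score", "household_size",
              "clinic_visits_3m", "opd_visits_3m", "inpatient_days_6m")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop_config("cohort CSV is missing columns: %s", paste(missing, collapse = ", "))
  n <- length(unique(records$participant_id))
  structure(list(records = records,
                 flow = list(screened = NA_integer_, screen_positive = NA_integer_,
                             enrolled = NA_integer_, excluded = NA_integer_,
                             retained = n),
                 log = character(), config = NULL),
            class = "perinatal_cohort")
}
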