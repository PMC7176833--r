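#' Gross (average) unit cost
#'
#' Divides total facility expenditure by total activity over the same period,
#' the standard top-down approach when ingredient-level costing is
#' unavailable.
#'
#' @param total_expenditure Total expenditure (money, >= 0).
#' @param activity_count Activity over the same period (e.g. patient
#'   headcount); must be > 0.
#' @param label Facility/service name used in error messages.
#' @return Cost per unit of activity.
#' @export
#' @examples
#' gross_unit_cost(117, 10) # 11.70
gross_unit_cost <- function(total_expenditure, activity_count, label = "service") {
  assert_nonneg(total_expenditure, "total_expenditure")
  if (any(activity_count <= 0))
    stop_config("division by zero: activity_count for '%s' must be > 0", label)
  total_expenditure / activity_count
}

#' Split hospital expenditure into inpatient-day and outpatient-visit costs
#'
#' Uses the patient day equivalent (PDE) convention: an outpatient department
#' visit is costed at one-third of an inpatient day. Total expenditure is
#' divided by `inpatient_days + opd_visits / 3` to give the cost per
#' inpatient day; the outpatient cost is a third of that. The split exactly
#' reallocates the input expenditure:
#' `inpatient_days * ipd_cost + opd_visits * opd_cost = total_expenditure`.
#'
#' @param total_expenditure Hospital expenditure (money, >= 0).
#' @param inpatient_days Inpatient days over the period.
#' @param opd_visits Outpatient department visits over the period.
#' @param label Facility name for error messages.
#' @return Named list with `cost_per_inpatient_day` and `cost_per_opd_visit`.
#' @export
#' @examples
#' patient_day_equivalent_split(120, inpatient_days = 30, opd_visits = 30)
patient_day_equivalent_split <- function(total_expenditure, inpatient_days,
                                         opd_visits, label = "hospital") {
  assert_nonneg(total_expenditure, "total_expenditure")
  assert_nonneg(inpatient_days, "inpatient_days")
  assert_nonneg(opd_visits, "opd_visits")
  pde <- inpatient_days + opd_visits / 3
  if (any(pde <= 0))
    stop_config("division by zero: '%s' has zero inpatient days and OPD visits", label)
  ipd <- total_expenditure / pde
  list(cost_per_inpatient_day = ipd, cost_per_opd_visit = ipd / 3)
}

#' Convert South African Rand to US dollars
#'
#' @param amount_zar Amount in ZAR.
#' @param zar_per_usd Exchange rate, ZAR per USD (default the 2014/15 average
#'   of 11.69).
#' @return Amount in USD.
#' @export
convert_currency <- function(amount_zar, zar_per_usd = 11.69) {
  if (any(!is.finite(zar_per_usd)) || any(zar_per_usd <= 0))
    stop_config("configuration error: zar_per_usd must be > 0")
  amount_zar / zar_per_usd
}

#' Provider unit-cost table from a facility finance table
#'
#' Computes average provider unit costs from facility-level expenditure and
#' activity data. Clinic (and community health centre) visit costs use gross
#' costing (expenditure over headcount, pooled across clinic rows); hospital
#' expenditure is split into inpatient-day and outpatient-visit unit costs by
#' the patient day equivalent method; delivery-day costs at midwife obstetric
#' units (MOU) and hospitals are gross-costed from their own expenditure and
#' delivery-day totals.
#'
#' The finance table needs columns `facility`, `service_type` (one of
#' `clinic`, `hospital`, `delivery_mou`, `delivery_hospital`),
#' `total_expenditure`, `headcount`, `inpatient_days`, `opd_visits`,
#' `delivery_days` (activity columns may be NA where not applicable; rows of
#' the same service type are pooled before division).
#'
#' @param finance Data frame as described, or a CSV path.
#' @param zar_per_usd Exchange rate used when reporting in USD.
#' @param price_year Price-year label carried through to reports.
#' @return An object of class `unit_cost_table`: unit costs in ZAR at the
#'   stated price year.
#' @export
build_unit_cost_table <- function(finance = synthetic_finance_table(),
                                  zar_per_usd = 11.69,
                                  price_year = "2014/15") {
  if (is.character(finance)) finance <- utils::read.csv(finance, stringsAsFactors = FALSE)
  needed <- c("facility", "service_type", "total_expenditure")
  missing <- setdiff(needed, names(finance))
  if (length(missing))
    stop_config("finance table is missing columns: %s", paste(missing, collapse = ", "))

  pool <- function(type, col) {
    rows <- finance[finance$service_type == type, , drop = FALSE]
    if (nrow(rows) == 0L)
      stop_config("finance table has no '%s' rows", type)
    list(expenditure = sum(rows$total_expenditure),
         activity = sum(rows[[col]], na.rm = TRUE),
         label = paste(unique(rows$facility), collapse = "+"))
  }

  cl <- pool("clinic", "headcount")
  cost_clinic <- gross_unit_cost(cl$expenditure, cl$activity, cl$label)

  hosp_rows <- finance[finance$service_type == "hospital", , drop = FALSE]
  if (nrow(hosp_rows) == 0L) stop_config("finance table has no 'hospital' rows")
  split <- patient_day_equivalent_split(
    sum(hosp_rows$total_expenditure),
    sum(hosp_rows$inpatient_days, na.rm = TRUE),
    sum(hosp_rows$opd_visits, na.rm = TRUE),
    paste(unique(hosp_rows$facility), collapse = "+")
  )

  dm <- pool("delivery_mou", "delivery_days")
  dh <- pool("delivery_hospital", "delivery_days")
  cost_del_mou <- gross_unit_cost(dm$expenditure, dm$activity, dm$label)
  cost_del_hosp <- gross_unit_cost(dh$expenditure, dh$activity, dh$label)

  structure(list(
    cost_per_clinic_visit = cost_clinic,
    cost_per_opd_visit = split$cost_per_opd_visit,
    cost_per_inpatient_day = split$cost_per_inpatient_day,
    cost_per_delivery_day_mou = cost_del_mou,
    cost_per_delivery_day_hospital = cost_del_hosp,
    currency = "ZAR",
    price_year = price_year,
    zar_per_usd = zar_per_usd
  ), class = "unit_cost_table")
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat(sprintf("Provider unit costs (%s, %s prices; %.2f ZAR/USD)\n",
              x$currency, x$price_year, x$zar_per_usd))
  for (nm in c("cost_per_clinic_visit", "cost_per_opd_visit",
               "cost_per_inpatient_day", "cost_per_delivery_day_mou",
               "cost_per_delivery_day_hospital")) {
    cat(sprintf("  %-32s %10.2f\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Synthetic provincial finance table
#'
#' A synthetic stand-in for audited provincial expenditure and activity data
#' (real facility finance data are not redistributable). Magnitudes are
#' chosen to yield unit costs plausible for South African public facilities
#' at 2014/15 prices: roughly R400 per clinic visit, R1200 per inpatient day
#' (OPD visit a third of that), R2500 per MOU delivery day and R5000 per
#' hospital delivery day.
#'
#' @return Data frame in the schema expected by [build_unit_cost_table()].
#' @export
synthetic_finance_table <- function() {
  data.frame(
    facility = c("PHC clinics (province)", "District hospitals (province)",
                 "MOUs (province)", "Obstetric wards (province)"),
    service_type = c("clinic", "hospital", "delivery_mou", "delivery_hospital"),
    total_expenditure = c(8.0e9, 3.0e9, 2.5e8, 6.0e8),
    headcount = c(2.0e7, NA, NA, NA),
    inpatient_days = c(NA, 1.5e6, NA, NA),
    opd_visits = c(NA, 3.0e6, NA, NA),
    delivery_days = c(NA, NA, 1.0e5, 1.2e5),
    stringsAsFactors = FALSE
  )
}
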