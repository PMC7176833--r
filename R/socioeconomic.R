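#' Midpoints of ordinal income categories
#'
#' Bounded categories use arithmetic midpoints; the right-open top category
#' uses its lower bound times `top_multiplier` (1.5 by default, standard
#' practice for open-ended bands).
#'
#' @param bounds List of `c(lower, upper)` pairs; upper may be `Inf` for the
#'   top band.
#' @param top_multiplier Multiplier for the open top category.
#' @return Numeric vector of midpoints, named by category label.
#' @export
income_category_midpoints <- function(bounds, top_multiplier = 1.5) {
  mids <- vapply(bounds, function(b) {
    if (any(b < 0) || b[2] <= b[1])
      stop_config("configuration error: income category bounds must be increasing and >= 0")
    if (is.infinite(b[2])) b[1] * top_multiplier else mean(b)
  }, numeric(1))
  names(mids) <- income_category_labels(bounds)
  mids
}

#' Impute continuous household income from categorical reports
#'
#' Household income collected in bands is converted to a continuous variable
#' by regressing the band midpoints on baseline employment, education and
#' socioeconomic status (the MCA wealth score) and taking fitted values,
#' clipped back to each respondent's reported band. Constant covariates are
#' dropped before fitting; a rank-deficient design falls back to the raw
#' category midpoints with a logged warning.
#'
#' @param income_category Character vector of reported band labels.
#' @param employed Logical vector, baseline employment.
#' @param education Character/factor vector, baseline education.
#' @param ses_score Numeric vector, baseline wealth (MCA) score.
#' @param category_bounds List of `c(lower, upper)` band bounds whose labels
#'   (via [income_category_midpoints()]) match `income_category`.
#' @param top_multiplier Passed to [income_category_midpoints()].
#' @return List with `income` (imputed values), `method` ("regression" or
#'   "midpoint"), `coefficients` (NULL for midpoint fallback) and `log`.
#' @export
impute_household_income <- function(income_category, employed, education,
                                    ses_score, category_bounds,
                                    top_multiplier = 1.5) {
  mids <- income_category_midpoints(category_bounds, top_multiplier)
  unknown <- setdiff(unique(income_category), names(mids))
  if (length(unknown))
    stop_config("configuration error: income categories without bounds: %s",
                paste(unknown, collapse = ", "))
  y <- mids[income_category]
  log <- character()

  covars <- list(employed = as.numeric(employed),
                 education = as.character(education),
                 ses_score = ses_score)
  keep <- vapply(covars, function(v) length(unique(v)) > 1L, logical(1))
  covars <- covars[keep]

  fallback <- function(msg) {
    list(income = unname(y), method = "midpoint", coefficients = NULL,
         log = c(log, msg))
  }
  if (length(covars) == 0L)
    return(fallback("all covariates constant; using category midpoints"))

  df <- data.frame(y = y, covars, stringsAsFactors = TRUE)
  fit <- stats::lm(y ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    return(fallback("singular design in income regression; using category midpoints"))

  pred <- unname(stats::fitted(fit))
  lower <- vapply(category_bounds, `[`, numeric(1), 1)[match(income_category, names(mids))]
  upper <- vapply(category_bounds, `[`, numeric(1), 2)[match(income_category, names(mids))]
  pred <- pmin(pmax(pred, lower), upper)
  list(income = pred, method = "regression",
       coefficients = stats::coef(fit), log = log)
}

#' Per-capita household income
#'
#' @param household_income Total household income.
#' @param household_size Number of household members (integer >= 1).
#' @return Income per household member.
#' @export
per_capita_income <- function(household_income, household_size) {
  assert_nonneg(household_income, "household_income")
  assert_count(household_size, "household_size", min = 1L)
  household_income / household_size
}

#' Wealth index by multiple correspondence analysis
#'
#' Performs correspondence analysis of the complete disjunctive (indicator)
#' matrix built from categorical asset and service-access variables: the
#' indicator matrix is converted to correspondence form (division by the
#' grand total, mass-weighted centring and scaling) and decomposed by SVD.
#' Row scores on the first principal dimension form the wealth index. The
#' sign is oriented so that a designated wealth-positive category (default:
#' electricity access) loads positively.
#'
#' Constant variables are dropped with a logged warning; an input with no
#' varying variable is an error.
#'
#' @param indicators Data frame of categorical variables (factor, character
#'   or logical), one row per participant.
#' @param wealth_positive Length-2 character vector `c(variable, category)`
#'   naming the category that must receive a positive column loading.
#' @return List with `scores` (first-dimension row principal coordinates,
#'   mean zero), `column_coordinates`, `inertia` (principal inertias of all
#'   dimensions) and `log`.
#' @export
mca_scores <- function(indicators,
                       wealth_positive = c("electricity", "TRUE")) {
  if (!is.data.frame(indicators) || ncol(indicators) < 1L)
    stop_config("validation error: indicators must be a data frame")
  indicators <- as.data.frame(lapply(indicators, as.character),
                              stringsAsFactors = FALSE)
  log <- character()
  varying <- vapply(indicators, function(v) length(unique(v)) > 1L, logical(1))
  if (any(!varying)) {
    log <- c(log, sprintf("dropped constant variable(s): %s",
                          paste(names(indicators)[!varying], collapse = ", ")))
    indicators <- indicators[, varying, drop = FALSE]
  }
  if (ncol(indicators) < 2L)
    stop_config("validation error: MCA needs at least 2 varying categorical variables")

  n <- nrow(indicators)
  blocks <- lapply(names(indicators), function(v) {
    f <- factor(indicators[[v]])
    z <- stats::model.matrix(~ f - 1)
    colnames(z) <- paste(v, levels(f), sep = ".")
    z
  })
  Z <- do.call(cbind, blocks)
  if (n < ncol(Z))
    stop_config("validation error: MCA needs at least as many rows as categories (%d < %d)",
                n, ncol(Z))

  # correspondence analysis of the indicator matrix
  P <- Z / sum(Z)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  sv <- svd(S)
  ndim <- sum(sv$d > 1e-12)
  if (ndim < 1L)
    stop_config("validation error: indicator matrix has no varying structure")

  row_scores <- unname((sv$u[, 1] / sqrt(r)) * sv$d[1])
  col_coords <- (sv$v[, 1] / sqrt(cm)) * sv$d[1]
  names(col_coords) <- colnames(Z)

  anchor <- paste(wealth_positive[1], wealth_positive[2], sep = ".")
  if (anchor %in% names(col_coords) && col_coords[[anchor]] < 0) {
    row_scores <- -row_scores
    col_coords <- -col_coords
  }

  list(scores = row_scores, column_coordinates = col_coords,
       inertia = sv$d[seq_len(ndim)]^2, log = log)
}

#' Cut wealth scores into ordered socioeconomic groups
#'
#' Quantile cut into `n_groups` equal-sized ordered groups; ties are broken
#' by stable participant order (the order of `ids`, or input order if `ids`
#' is NULL).
#'
#' @param scores Numeric wealth scores.
#' @param n_groups Number of groups (default 2: poorer/richer).
#' @param ids Optional identifiers used for stable tie-breaking.
#' @return Ordered factor of group labels (`poorer`/`richer` for 2 groups,
#'   else `q1`..`qk`).
#' @export
assign_ses_groups <- function(scores, n_groups = 2L, ids = NULL) {
  if (any(!is.finite(scores)))
    stop_config("validation error: scores must be finite")
  assert_count(n_groups, "n_groups", min = 2L)
  if (length(unique(scores)) < n_groups)
    stop_config("validation error: fewer distinct scores (%d) than groups (%d)",
                length(unique(scores)), n_groups)
  n <- length(scores)
  if (is.null(ids)) ids <- seq_len(n)
  ord <- order(scores, ids)
  grp <- integer(n)
  grp[ord] <- ceiling(seq_len(n) * n_groups / n)
  labels <- if (n_groups == 2L) c("poorer", "richer")
            else paste0("q", seq_len(n_groups))
  factor(labels[grp], levels = labels, ordered = TRUE)
}

#' Kruskal-Wallis comparison of a quantitative outcome across groups
#'
#' Rank-based H statistic with tie correction against a chi-squared
#' reference with k-1 degrees of freedom (delegates to
#' [stats::kruskal.test()]).
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @return A `group_comparison` list: `test_name`, `statistic`, `p_value`,
#'   `group_summaries` (n and mean per group).
#' @export
kruskal_wallis <- function(values_by_group) {
  if (length(values_by_group) < 2L || any(lengths(values_by_group) < 1L))
    stop_config("validation error: need >= 2 non-empty groups")
  kt <- stats::kruskal.test(values_by_group)
  structure(list(
    test_name = "kruskal_wallis",
    statistic = unname(kt$statistic),
    p_value = kt$p.value,
    group_summaries = data.frame(
      group = names(values_by_group) %||% seq_along(values_by_group),
      n = lengths(values_by_group),
      mean = vapply(values_by_group, mean, numeric(1)),
      row.names = NULL
    )
  ), class = "group_comparison")
}

#' Pearson chi-squared test of independence on a contingency table
#'
#' Uncorrected Pearson chi-squared of observed against expected counts under
#' independence (delegates to [stats::chisq.test()] without continuity
#' correction). Expected cells below 1 are recorded in the result's `log`.
#'
#' @param contingency_table Matrix or table of non-negative counts.
#' @return A `group_comparison` list: `test_name`, `statistic`, `p_value`,
#'   `group_summaries` (row proportions), `log`.
#' @export
pearson_chi2 <- function(contingency_table) {
  tab <- as.matrix(contingency_table)
  if (any(tab < 0)) stop_config("validation error: table cells must be >= 0")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  log <- character()
  if (any(ct$expected < 1))
    log <- "expected cell count below 1; chi-squared approximation unreliable"
  props <- prop.table(tab, margin = 1)
  structure(list(
    test_name = "pearson_chi2",
    statistic = unname(ct$statistic),
    p_value = ct$p.value,
    group_summaries = as.data.frame.matrix(props),
    log = log
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g\n", x$test_name, x$statistic, x$p_value))
  print(x$group_summaries)
  invisible(x)
}
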