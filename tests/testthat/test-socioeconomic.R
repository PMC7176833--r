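test_that("income band midpoints use arithmetic means and a 1.5x open top", {
  bounds <- list(c(0, 1000), c(1000, 2000), c(6000, Inf))
  mids <- income_category_midpoints(bounds)
  expect_equal(unname(mids), c(500, 1500, 9000))
  expect_error(income_category_midpoints(list(c(5, 2))), "increasing")
})

test_that("income imputation collapses to midpoints when nothing varies", {
  bounds <- list(c(0, 100), c(100, 200))
  res <- impute_household_income(rep("0-100", 5), employed = rep(TRUE, 5),
                                 education = rep("primary", 5),
                                 ses_score = rep(0, 5), bounds)
  expect_identical(res$method, "midpoint")
  expect_equal(res$income, rep(50, 5))
  # constant outcome with varying covariates: regression fits the constant
  res2 <- impute_household_income(rep("0-100", 5), employed = c(T, F, T, F, T),
                                  education = rep("primary", 5),
                                  ses_score = rnorm(5), bounds)
  expect_identical(res2$method, "regression")
  expect_equal(res2$income, rep(50, 5))
})

test_that("income imputation recovers a noiseless generating model", {
  # band midpoints constructed to equal 2 + 3*employed + 5*ses exactly
  bounds <- list(c(0, 4), c(4, 6), c(6, 8), c(8, 12))
  labs <- names(income_category_midpoints(bounds))
  grid <- expand.grid(employed = c(0, 1), ses = c(0, 1))
  grid <- grid[rep(1:4, 10), ]
  y <- 2 + 3 * grid$employed + 5 * grid$ses
  category <- labs[match(y, c(2, 5, 7, 10))]
  res <- impute_household_income(category, employed = grid$employed == 1,
                                 education = rep("matric_plus", nrow(grid)),
                                 ses_score = grid$ses, bounds)
  expect_identical(res$method, "regression")
  co <- res$coefficients
  expect_equal(unname(co[["(Intercept)"]]), 2, tolerance = 1e-6)
  expect_equal(unname(co[["employed"]]), 3, tolerance = 1e-6)
  expect_equal(unname(co[["ses_score"]]), 5, tolerance = 1e-6)
  expect_equal(res$income, y, tolerance = 1e-6)
})

test_that("imputed income is clipped to the reported band", {
  bounds <- list(c(0, 100), c(100, 200), c(200, 300))
  labs <- names(income_category_midpoints(bounds))
  category <- labs[c(1, 2, 3, 2)]
  ses <- c(0, 1, 2, 2)  # the 4th respondent's unclipped prediction exceeds 200
  res <- impute_household_income(category, employed = rep(FALSE, 4),
                                 education = rep("primary", 4), ses, bounds)
  expect_identical(res$method, "regression")
  expect_equal(res$income[4], 200)
  expect_true(all(res$income >= c(0, 100, 200, 100)))
  expect_error(impute_household_income("no-such-band", TRUE, "primary", 0, bounds),
               "without bounds")
})

test_that("per-capita income divides by household size and reconstructs", {
  expect_equal(per_capita_income(600, 4), 150)
  expect_equal(per_capita_income(0, 3), 0)
  expect_equal(per_capita_income(59.84 * 5, 5), 59.84)
  set.seed(31)
  inc <- runif(50, 0, 1e4)
  size <- 1L + rpois(50, 3)
  expect_equal(per_capita_income(inc, size) * size, inc, tolerance = 1e-12)
  expect_error(per_capita_income(100, 0), "household_size")
})

test_that("MCA separates perfectly aligned participant blocks", {
  ind <- data.frame(
    electricity = c(rep("TRUE", 3), rep("FALSE", 3)),
    bank = c(rep("yes", 3), rep("no", 3)),
    stringsAsFactors = FALSE
  )
  res <- mca_scores(ind)
  s <- res$scores
  expect_equal(stats::var(s[1:3]), 0, tolerance = 1e-12)
  expect_equal(stats::var(s[4:6]), 0, tolerance = 1e-12)
  expect_true(s[1] != s[4])
  # wealth-positive anchor (electricity TRUE) loads positively
  expect_gt(s[1], s[4])
  expect_equal(mean(s), 0, tolerance = 1e-12)
})

test_that("permuting participants permutes MCA scores identically", {
  set.seed(33)
  ind <- data.frame(
    electricity = sample(c("TRUE", "FALSE"), 30, TRUE),
    water = sample(c("tap", "none"), 30, TRUE),
    shop = sample(c("supermarket", "spaza"), 30, TRUE),
    stringsAsFactors = FALSE
  )
  base <- mca_scores(ind)$scores
  perm <- sample(30)
  permuted <- mca_scores(ind[perm, , drop = FALSE])$scores
  expect_equal(permuted, base[perm], tolerance = 1e-10)
})

test_that("constant indicators are dropped and degenerate input errors", {
  ind <- data.frame(a = c("x", "x", "y", "y"), b = rep("z", 4),
                    c = c("p", "q", "p", "q"), stringsAsFactors = FALSE)
  res <- mca_scores(ind)
  expect_true(any(grepl("constant", res$log)))
  expect_error(mca_scores(data.frame(a = rep("x", 4), b = rep("z", 4))),
               "varying")
})

test_that("SES quantile groups are ordered, balanced and stable under ties", {
  expect_identical(as.character(assign_ses_groups(c(-1, 1))), c("poorer", "richer"))
  expect_error(assign_ses_groups(rep(2, 10)), "distinct")
  set.seed(35)
  g <- assign_ses_groups(rnorm(100))
  expect_equal(as.integer(table(g)), c(50L, 50L))
  # tied scores are split by participant-id order, deterministically
  scores <- c(0, 1, 1, 1, 2, 3)
  g2 <- assign_ses_groups(scores, ids = c("a", "b", "c", "d", "e", "f"))
  expect_identical(as.character(g2), c("poorer", "poorer", "poorer",
                                       "richer", "richer", "richer"))
})

test_that("group comparison wrappers report identity, statistic and p-value", {
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_identical(kw$test_name, "kruskal_wallis")
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p_value, 1)
  expect_equal(kw$group_summaries$n, c(3L, 3L))

  tab <- rbind(c(20, 10), c(40, 20))  # equal row proportions
  ch <- pearson_chi2(tab)
  expect_identical(ch$test_name, "pearson_chi2")
  expect_equal(ch$statistic, 0, tolerance = 1e-12)
  expect_equal(ch$p_value, 1, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(a = 1:3)), "2 non-empty")
  expect_error(pearson_chi2(rbind(c(-1, 2), c(3, 4))), ">= 0")
  small <- pearson_chi2(rbind(c(1, 0), c(0, 1)))
  expect_true(any(grepl("below 1", small$log)))
})
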