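test_that("a single binary predictor reproduces the closed-form 2x2 odds ratio", {
  set.seed(2)
  n <- 5000L
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 1.2 * x))
  ft <- data.table::data.table(
    member_id = as.character(seq_len(n)),
    outcome = factor(ifelse(y == 1, "CASE", "CTRL"),
                     levels = c("CTRL", "CASE")),
    exposure = x)
  data.table::setattr(ft, "reference", "CTRL")
  fit <- fit_mlogit_l1(ft, cv_folds = 3, seed = 1)
  tab <- table(x, y)
  closed <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_equal(fit$table$or, closed, tolerance = 0.01)
})

test_that("pure-noise predictors are discarded or shrunk to null odds ratios", {
  set.seed(3)
  n <- 5000L
  ft <- data.table::data.table(
    member_id = as.character(seq_len(n)),
    outcome = factor(sample(c("A", "B"), n, replace = TRUE)),
    n1 = rbinom(n, 1, 0.5), n2 = rbinom(n, 1, 0.3), n3 = rnorm(n),
    n4 = rnorm(n), n5 = rbinom(n, 1, 0.2), n6 = rnorm(n),
    n7 = rbinom(n, 1, 0.4), n8 = rnorm(n))
  data.table::setattr(ft, "continuous", c("n3", "n4", "n6", "n8"))
  res <- tryCatch(fit_mlogit_l1(ft, cv_folds = 3, seed = 2),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "selected no features")
  } else {
    expect_lte(length(res$selected), 3L)
    expect_true(all(abs(log(res$table$or)) < 0.25))
  }
})

test_that("at most one of two perfectly collinear predictors survives", {
  set.seed(4)
  n <- 4000L
  x <- rbinom(n, 1, 0.4)
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 1.0 * x + 0.5 * z))
  ft <- data.table::data.table(
    member_id = as.character(seq_len(n)),
    outcome = factor(ifelse(y == 1, "CASE", "CTRL"),
                     levels = c("CTRL", "CASE")),
    dup1 = x, dup2 = x, other = z)
  data.table::setattr(ft, "continuous", "other")
  fit <- fit_mlogit_l1(ft, cv_folds = 3, seed = 3)
  expect_lte(sum(c("dup1", "dup2") %in% fit$selected), 1L)
})

test_that("refit recovers known multinomial-logit coefficients", {
  # across 20 seeds, >= 95% of the 24 truth coefficients (2 classes x 6
  # predictors x 2 stats... 12 coefficients per seed) fall within 3 SEs
  n_within <- 0L
  n_total <- 0L
  for (seed in 1:20) {
    sim <- simulate_mlogit_truth(20000L, seed)
    fit <- fit_mlogit_l1(sim$features, cv_folds = 3, seed = seed)
    for (cl in c("B", "C")) {
      tab <- fit$table[class_label == cl]
      truth <- sim$truth[[cl]][match(tab$feature, colnames(sim$features)[3:8])]
      within <- abs(log(tab$or) - truth) <= 3 * tab$se
      n_within <- n_within + sum(within)
      n_total <- n_total + length(within)
    }
  }
  expect_gte(n_within / n_total, 0.95)
})

test_that("switching the reference class rescales odds ratios consistently", {
  sim <- simulate_mlogit_truth(8000L, 99)
  fit_a <- fit_mlogit_l1(sim$features, cv_folds = 3, seed = 5,
                         reference = "A")
  fit_b <- fit_mlogit_l1(sim$features, cv_folds = 3, seed = 5,
                         reference = "B")
  expect_setequal(fit_a$selected, fit_b$selected)
  for (f in fit_a$selected) {
    or_c_vs_a <- fit_a$table[feature == f & class_label == "C", or]
    or_b_vs_a <- fit_a$table[feature == f & class_label == "B", or]
    or_c_vs_b <- fit_b$table[feature == f & class_label == "C", or]
    expect_equal(or_c_vs_b, or_c_vs_a / or_b_vs_a, tolerance = 0.02)
  }
})

test_that("reported binary odds ratios are invariant to continuous rescaling", {
  sim <- simulate_mlogit_truth(8000L, 7)
  ft2 <- data.table::copy(sim$features)
  ft2[, c1 := c1 * 100]
  fit1 <- fit_mlogit_l1(sim$features, cv_folds = 3, seed = 11)
  fit2 <- fit_mlogit_l1(ft2, cv_folds = 3, seed = 11)
  for (f in intersect(c("b1", "b2", "b3"),
                      intersect(fit1$selected, fit2$selected))) {
    expect_equal(fit1$table[feature == f, or],
                 fit2$table[feature == f, or], tolerance = 1e-4)
  }
})

test_that("small or degenerate outcome classes are rejected", {
  sim <- simulate_mlogit_truth(500L, 1)
  ft <- sim$features[1:120]
  expect_error(fit_mlogit_l1(ft, cv_folds = 3, seed = 1), "at least 50 rows")
})

test_that("spend-group features use year-t predictors and year-t+1 outcomes", {
  panel <- generate_population(small_config(3000), seed = 43)
  inc <- filter_continuous_enrollment(panel, cohort_spec(2016, 2019, TRUE))
  seg <- segment_panel(inc)
  ft <- build_spend_group_features(inc, seg$groups, 2016)
  g17 <- seg$groups[year == 2017]
  expect_setequal(levels(ft$outcome),
                  c("BOTTOM90", "CATASTROPHIC", "PERSISTENT",
                    "SEMI_PERSISTENT"))
  m <- merge(ft[, .(member_id, outcome)], g17, by = "member_id")
  expect_identical(as.character(m$outcome), m$group)
  # temporal separation: permuting year-2017+ panel data leaves predictors
  # unchanged
  perm <- data.table::copy(inc)
  perm[year >= 2017, total_cost := rev(total_cost)]
  perm[year >= 2017, hospital_days := rev(hospital_days)]
  ft_perm <- build_spend_group_features(perm, seg$groups, 2016)
  expect_identical(ft_perm[, !"outcome"], ft[, !"outcome"])
})

test_that("persistence outcome counts top-decile years over the horizon", {
  panel <- generate_population(small_config(2000), seed = 47)
  inc <- filter_continuous_enrollment(panel, cohort_spec(2016, 2019, TRUE))
  dp <- decile_pipeline(inc)
  ft <- build_persistence_features(inc, dp$assignments, 2016)
  top_years <- dp$assignments[decile == 10L & year >= 2017,
                              .(n_top = .N), by = member_id]
  m <- merge(ft[, .(member_id, outcome)], top_years,
             by = "member_id", all.x = TRUE)
  m[is.na(n_top), n_top := 0L]
  expect_identical(as.integer(as.character(m$outcome)), as.integer(m$n_top))
  expect_error(build_persistence_features(inc, dp$assignments[year < 2019],
                                          2016),
               "four panel years")
})

test_that("ESRD raises the odds of persistent membership on generated data", {
  panel <- generate_population(small_config(20000), seed = 53)
  inc <- filter_continuous_enrollment(panel, cohort_spec(2016, 2019, TRUE))
  seg <- segment_panel(inc)
  ft <- build_spend_group_features(inc, seg$groups, 2016)
  fit <- fit_mlogit_l1(ft, cv_folds = 3, seed = 7)
  expect_true("esrd_or_dialysis" %in% fit$selected)
  or_pers <- fit$table[feature == "esrd_or_dialysis" &
                         class_label == "PERSISTENT", or]
  expect_gt(or_pers, 1)
})
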