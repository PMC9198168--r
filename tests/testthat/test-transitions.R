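# hand-built flow fixture: 4 persistent members at t; at t+1 two stay
# persistent, one dies, one drops to decile 5
toy_flow_inputs <- function() {
  groups_t <- data.table::data.table(
    member_id = c("F1", "F2", "F3", "F4"), year = 2017,
    group = "PERSISTENT", criteria_fired = "CHRONIC_DRUG",
    prior_year_below_p60 = FALSE)
  groups_t1 <- data.table::data.table(
    member_id = c("F1", "F2", "F4"), year = 2018,
    group = c("PERSISTENT", "PERSISTENT", "BOTTOM90"),
    criteria_fired = c("CHRONIC_DRUG", "CHRONIC_DRUG", ""),
    prior_year_below_p60 = FALSE)
  assignments_t1 <- data.table::data.table(
    member_id = c("F1", "F2", "F4"), year = 2018,
    decile = c(10L, 10L, 5L), rank_in_year = c(39L, 40L, 20L))
  list(groups_t = groups_t, groups_t1 = groups_t1,
       assignments_t1 = assignments_t1, deaths_t1 = "F3")
}

test_that("group flows match the hand-enumerated toy example", {
  x <- toy_flow_inputs()
  fl <- group_flows(x$groups_t, x$groups_t1, x$assignments_t1, x$deaths_t1)
  pr <- fl$row_proportions["PERSISTENT", ]
  expect_equal(unname(pr["PERSISTENT"]), 0.50)
  expect_equal(unname(pr["DIED"]), 0.25)
  expect_equal(unname(pr["P0_60"]), 0.25)
  expect_equal(sum(fl$counts["PERSISTENT", ]), 4L)
})

test_that("a fully dying origin row routes entirely to DIED", {
  x <- toy_flow_inputs()
  fl <- group_flows(x$groups_t, x$groups_t1[0], x$assignments_t1[0],
                    deaths_t1 = c("F1", "F2", "F3", "F4"))
  expect_equal(unname(fl$row_proportions["PERSISTENT", "DIED"]), 1)
})

test_that("an origin member with no destination state errors", {
  x <- toy_flow_inputs()
  expect_error(group_flows(x$groups_t, x$groups_t1[member_id != "F4"],
                           x$assignments_t1[member_id != "F4"], x$deaths_t1),
               "missing from both")
})

test_that("one-year mortality is deaths over at-risk", {
  groups <- data.table::data.table(
    member_id = sprintf("M%02d", 1:10), year = 2017,
    group = "SEMI_PERSISTENT", criteria_fired = "",
    prior_year_below_p60 = FALSE)
  m <- one_year_mortality(groups, deaths_t1 = c("M01", "M02"))
  expect_equal(m$rate, 0.2)
  expect_equal(m$deaths, 2L)
  expect_equal(m$at_risk, 10L)
  m0 <- one_year_mortality(groups, deaths_t1 = character(0))
  expect_equal(m0$rate, 0)
})

test_that("flow DIED proportions equal one-year mortality on a common cohort", {
  panel <- generate_population(small_config(4000), seed = 23)
  inc <- filter_continuous_enrollment(panel, cohort_spec(2016, 2019, TRUE))
  seg <- segment_panel(inc)
  g17 <- seg$groups[year == 2017]
  g18 <- seg$groups[year == 2018]
  origins <- g17[group %in% c("CATASTROPHIC", "PERSISTENT", "SEMI_PERSISTENT") &
                   !member_id %in% deaths_in_year(inc, 2017)]
  deaths18 <- deaths_in_year(inc, 2018)
  fl <- group_flows(origins, g18, seg$assignments, deaths18)
  mr <- one_year_mortality(origins, deaths18)
  for (g in rownames(fl$counts)) {
    expect_equal(unname(fl$row_proportions[g, "DIED"]),
                 mr[group == g, rate])
  }
  # conservation: each origin row's count equals the origin group size
  expect_equal(unname(rowSums(fl$counts)),
               unname(table(factor(origins$group,
                                   levels = rownames(fl$counts)))),
               ignore_attr = TRUE)
  # structural zero: no top-decile origin can become catastrophic
  expect_equal(sum(fl$counts[, "CATASTROPHIC"]), 0L)
})

test_that("pharmacy persistence matches a hand-enumerated 5-member chain", {
  # five top-decile members in 2017; ratios >= 0.6 for H1, H2, H3;
  # H1 and H2 stay top-decile in 2018; H1 keeps ratio >= 0.6 in 2018 and
  # 2019, H2 drops below in 2019
  mk <- function(id, year, total, pharm, rank) {
    member_year_row(id, year, total, pharmacy_cost = pharm)
  }
  rows <- list(
    mk("H1", 2017, 1000, 700), mk("H2", 2017, 1000, 650),
    mk("H3", 2017, 1000, 620), mk("H4", 2017, 1000, 100),
    mk("H5", 2017, 1000, 0),
    mk("H1", 2018, 1000, 700), mk("H2", 2018, 1000, 800),
    mk("H3", 2018, 1000, 100), mk("H4", 2018, 1000, 100),
    mk("H5", 2018, 1000, 0),
    mk("H1", 2019, 1000, 660), mk("H2", 2019, 1000, 100),
    mk("H3", 2019, 1000, 100), mk("H4", 2019, 1000, 100),
    mk("H5", 2019, 1000, 0))
  panel <- data.table::rbindlist(rows)
  assignments <- data.table::data.table(
    member_id = rep(sprintf("H%d", 1:5), 3),
    year = rep(2017:2019, each = 5),
    decile = c(10L, 10L, 10L, 10L, 10L,   # 2017: all top
               10L, 10L, 4L, 10L, 10L,    # 2018: H3 drops out
               10L, 10L, 4L, 10L, 10L),
    rank_in_year = 1L)
  pp <- pharmacy_persistence(panel, assignments, 2017:2019)
  expect_equal(pp$share_of_top_decile_with_high_pharmacy, 3 / 5)
  expect_equal(pp$retention_next_year, 2 / 3)
  expect_equal(pp$pharmacy_dominance_retention_two_years, 1 / 2)
  expect_equal(pp$n_high_pharmacy, 3L)
})

test_that("pharmacy persistence handles an empty high-pharmacy stratum", {
  panel <- data.table::rbindlist(lapply(2017:2019, function(y) {
    data.table::rbindlist(lapply(1:12, function(i) {
      member_year_row(sprintf("Z%02d", i), y, 100 * i, pharmacy_cost = 10)
    }))
  }))
  dp <- decile_pipeline(panel)
  pp <- pharmacy_persistence(panel, dp$assignments, 2017:2019)
  expect_equal(pp$share_of_top_decile_with_high_pharmacy, 0)
  expect_true(is.na(pp$retention_next_year))
})

test_that("frailty cost contrast reduces to a ratio of means", {
  rows <- list()
  for (i in 1:8) {
    id <- sprintf("G%02d", i)
    frail <- i <= 4
    for (y in 2016:2018) {
      rows[[length(rows) + 1L]] <- member_year_row(
        id, y, 1000,
        inpatient_cost = if (y >= 2017) (if (frail) 125 else 100) else 50,
        frailty_components = if (frail) "mobility" else "")
    }
  }
  panel <- data.table::rbindlist(rows)
  groups <- data.table::data.table(
    member_id = sprintf("G%02d", 1:8), year = 2017,
    group = "SEMI_PERSISTENT", criteria_fired = "",
    prior_year_below_p60 = FALSE)
  ct <- frailty_cost_contrast(panel, groups, 2017)
  expect_equal(unname(ct["h0"]), 0.25)
  expect_equal(unname(ct["h1"]), 0.25)
})

test_that("frailty contrast is positive on the calibrated generator", {
  panel <- generate_population(small_config(40000), seed = 29)
  inc <- filter_continuous_enrollment(panel, cohort_spec(2016, 2019, TRUE))
  seg <- segment_panel(inc)
  ct <- frailty_cost_contrast(inc, seg$groups[year == 2017], 2017)
  expect_gt(ct["h0"], 0)
  expect_gt(ct["h1"], 0)
})
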