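# 30-member two-year panel with known structure: costs 1..30 in 2017 place
# members T..28-30 in the top decile; 2016 costs control the catastrophic
# rule (P60 of 2016 = cost of rank 18).
segmentation_fixture <- function() {
  rows <- list()
  for (i in 1:30) {
    id <- sprintf("S%02d", i)
    cost16 <- i * 10          # rank order preserved: P60 threshold = 180
    cost17 <- i * 100
    rows[[length(rows) + 1L]] <- member_year_row(id, 2016, cost16, age = 70L)
    rows[[length(rows) + 1L]] <- member_year_row(id, 2017, cost17, age = 71L)
  }
  data.table::rbindlist(rows)
}

classify_fixture <- function(panel) {
  dp <- decile_pipeline(panel)
  classify_groups(panel, dp$assignments, dp$thresholds, 2017)
}

test_that("catastrophic takes precedence over persistent criteria", {
  panel <- segmentation_fixture()
  # member 28 becomes a cost shock: 2016 cost below P60 (180), top decile 2017,
  # and carries ESRD -- must still be catastrophic
  panel[member_id == "S28" & year == 2016, total_cost := 50]
  panel[member_id == "S28", esrd_or_dialysis := TRUE]
  g <- classify_fixture(panel)
  expect_identical(g[member_id == "S28", group], "CATASTROPHIC")
  expect_identical(g[member_id == "S28", criteria_fired], "")
  expect_true(g[member_id == "S28", prior_year_below_p60])
})

test_that("pharmacy-dominated top-decile spenders are persistent", {
  panel <- segmentation_fixture()
  panel[member_id == "S29" & year == 2017,
        `:=`(pharmacy_cost = 0.75 * total_cost,
             inpatient_cost = 0.10 * total_cost,
             outpatient_cost = 0.10 * total_cost,
             physician_cost = 0.05 * total_cost)]
  g <- classify_fixture(panel)
  expect_identical(g[member_id == "S29", group], "PERSISTENT")
  expect_identical(g[member_id == "S29", criteria_fired], "PHARMACY_RATIO")
  # exactly at the 60% boundary the criterion still fires ("at or above")
  panel[member_id == "S30" & year == 2017,
        `:=`(pharmacy_cost = 0.60 * total_cost,
             inpatient_cost = 0.20 * total_cost,
             outpatient_cost = 0.10 * total_cost,
             physician_cost = 0.10 * total_cost)]
  g <- classify_fixture(panel)
  expect_identical(g[member_id == "S30", group], "PERSISTENT")
})

test_that("top-decile members with no criteria are semi-persistent", {
  g <- classify_fixture(segmentation_fixture())
  expect_identical(g[member_id %in% sprintf("S%02d", 28:30), unique(group)],
                   "SEMI_PERSISTENT")
  expect_identical(g[member_id == "S10", group], "BOTTOM90")
})

test_that("the under-65-at-baseline criterion uses the first panel year", {
  panel <- segmentation_fixture()
  panel[member_id == "S30" & year == 2016, age := 64L]
  panel[member_id == "S30" & year == 2017, age := 65L]
  g <- classify_fixture(panel)
  expect_identical(g[member_id == "S30", group], "PERSISTENT")
  expect_identical(g[member_id == "S30", criteria_fired], "UNDER_65_2016")
})

test_that("chronic_drug_flag matches the five defining classes only", {
  rows <- data.table::rbindlist(list(
    member_year_row("D1", 2017, 100, drug_categories = "dmard"),
    member_year_row("D2", 2017, 100, drug_categories = ""),
    member_year_row("D3", 2017, 100, drug_categories = "ahfs24"),
    member_year_row("D4", 2017, 100, drug_categories = "ahfs24;hiv_nrti"),
    member_year_row("D5", 2017, 100, drug_categories = "antineoplastic")))
  expect_identical(chronic_drug_flag(rows), c(TRUE, FALSE, FALSE, TRUE, TRUE))
})

test_that("pharmacy_ratio handles boundaries and zero totals", {
  rows <- data.table::rbindlist(list(
    member_year_row("P1", 2017, 100, pharmacy_cost = 60),
    member_year_row("P2", 2017, 100, pharmacy_cost = 0),
    member_year_row("P3", 2017, 0, pharmacy_cost = 0)))
  expect_equal(pharmacy_ratio(rows), c(0.6, 0, 0))
})

test_that("the three groups partition the top decile exactly", {
  panel <- generate_population(small_config(3000), seed = 17)
  inc <- filter_continuous_enrollment(panel, cohort_spec(2016, 2019, TRUE))
  dp <- decile_pipeline(inc)
  for (y in 2017:2019) {
    g <- classify_groups(inc, dp$assignments, dp$thresholds, y)
    a <- dp$assignments[year == y]
    top <- a[decile == 10L, member_id]
    expect_setequal(g[group != "BOTTOM90", member_id], top)
    expect_setequal(g[group == "BOTTOM90", member_id],
                    a[decile < 10L, member_id])
  }
})

test_that("no member under 65 at baseline is ever semi-persistent", {
  panel <- generate_population(small_config(4000), seed = 19)
  inc <- filter_continuous_enrollment(panel, cohort_spec(2016, 2019, TRUE))
  seg <- segment_panel(inc)
  base_age <- inc[year == 2016, .(member_id, age)]
  semi <- seg$groups[group == "SEMI_PERSISTENT"]
  expect_true(all(base_age[match(semi$member_id, member_id), age] >= 65))
})

test_that("classification is a pure function of its inputs", {
  panel <- random_small_panel(n = 40, seed = 5)
  dp <- decile_pipeline(panel)
  g1 <- classify_groups(panel, dp$assignments, dp$thresholds, 2017)
  g2 <- classify_groups(panel, dp$assignments, dp$thresholds, 2017)
  expect_identical(g1, g2)
})

test_that("classification agrees with the brute-force oracle", {
  for (seed in 1:10) {
    panel <- random_small_panel(n = 40, seed = seed)
    dp <- decile_pipeline(panel)
    g <- classify_groups(panel, dp$assignments, dp$thresholds, 2017)
    o <- oracle_classify(panel, 2017)
    m <- merge(as.data.frame(g[, .(member_id, group)]), o, by = "member_id")
    expect_identical(m$group.x, m$group.y)
  }
})

test_that("classification requires a classifiable year and prior rows", {
  panel <- segmentation_fixture()
  dp <- decile_pipeline(panel)
  expect_error(classify_groups(panel, dp$assignments, dp$thresholds, 2016),
               "first panel year")
  broken <- panel[!(member_id == "S30" & year == 2016)]
  dpb <- decile_pipeline(broken)
  expect_error(classify_groups(broken, dpb$assignments, dpb$thresholds, 2017),
               "no year 2016 row")
})
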