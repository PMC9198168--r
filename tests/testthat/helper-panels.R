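# Hand-built member-year rows and independent brute-force oracles used
# across the suite. Oracles are deliberately written as straight-line loops,
# sharing no code with the package implementation.

full_months <- paste(1:12, collapse = ";")

member_year_row <- function(member_id, year, total_cost,
                            pharmacy_cost = 0,
                            inpatient_cost = NULL,
                            enrolled_months = full_months,
                            death_month = NA_integer_,
                            age = 72L,
                            esrd_or_dialysis = FALSE,
                            drug_categories = "",
                            frailty_components = "",
                            chronic_conditions = "cc01",
                            hospital_days = 0L,
                            sex = "F",
                            dual_eligible = FALSE) {
  inpatient_cost <- inpatient_cost %||% round(0.3 * (total_cost - pharmacy_cost), 2)
  rest <- total_cost - pharmacy_cost - inpatient_cost
  data.table::data.table(
    member_id = member_id, year = as.integer(year),
    total_cost = total_cost, pharmacy_cost = pharmacy_cost,
    inpatient_cost = inpatient_cost,
    outpatient_cost = round(rest / 2, 2),
    physician_cost = total_cost - pharmacy_cost - inpatient_cost -
      round(rest / 2, 2),
    hospital_days = hospital_days, enrolled_months = enrolled_months,
    death_month = death_month, age = as.integer(age), sex = sex,
    race = "White", dual_eligible = dual_eligible, ses_index = 52.5,
    geography = "urban", chronic_conditions = chronic_conditions,
    frailty_components = frailty_components,
    drug_categories = drug_categories, procedure_categories = "ccs04",
    esrd_or_dialysis = esrd_or_dialysis, distinct_providers = 3L,
    distinct_specialties = 2L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# panel of n members over the given years with per-member-year costs given
# as an n x length(years) matrix
panel_from_costs <- function(cost_matrix, years, ...) {
  n <- nrow(cost_matrix)
  ids <- sprintf("T%04d", seq_len(n))
  data.table::rbindlist(lapply(seq_along(years), function(j) {
    data.table::rbindlist(lapply(seq_len(n), function(i) {
      member_year_row(ids[i], years[j], cost_matrix[i, j], ...)
    }))
  }))
}

# small config for fast generator runs
small_config <- function(n = 400L) {
  cfg <- spendseg::default_config()
  cfg$n_members <- as.integer(n)
  cfg
}

# single-archetype config: all mass on one archetype, optionally no deaths
# and no events
mono_config <- function(archetype, n = 100L, no_death = FALSE,
                        no_events = FALSE) {
  cfg <- small_config(n)
  cfg$archetype_mix[] <- 0
  cfg$archetype_mix[archetype] <- 1
  cfg$gap_probability <- 0
  if (no_death) {
    for (a in names(cfg$archetypes)) {
      cfg$archetypes[[a]]$death$intercept <- -Inf
    }
  }
  if (no_events) {
    for (a in names(cfg$archetypes)) {
      cfg$archetypes[[a]]$event$prob <- 0
      cfg$archetypes[[a]]$drugs$annual_incidence <- 0
    }
  }
  cfg
}

## ---- independent oracles --------------------------------------------------

# sort-and-slice decile reference: returns decile per input position
oracle_deciles <- function(costs, ids) {
  n <- length(costs)
  ord <- order(costs, ids)
  dec <- integer(n)
  for (r in seq_len(n)) {
    # member with rank r falls in the block (k-1)*n/10 < r <= k*n/10
    k <- 1L
    while (r > k * n / 10) k <- k + 1L
    dec[ord[r]] <- k
  }
  dec
}

# straight-line reimplementation of the four segmentation rules for one year
oracle_classify <- function(panel, year) {
  panel <- as.data.frame(panel)
  rows_t <- panel[panel$year == year, ]
  rows_p <- panel[panel$year == year - 1, ]
  rows_b <- panel[panel$year == min(panel$year), ]
  n <- nrow(rows_t)
  dec <- oracle_deciles(rows_t$total_cost, rows_t$member_id)
  # prior-year P60: cost of the member at rank ceiling(6 n/10)
  pc <- rows_p$total_cost[order(rows_p$total_cost, rows_p$member_id)]
  p60 <- pc[ceiling(6 * length(pc) / 10)]
  out <- character(n)
  drugs5 <- spendseg::persistent_drug_classes()
  for (i in seq_len(n)) {
    if (dec[i] != 10) { out[i] <- "BOTTOM90"; next }
    id <- rows_t$member_id[i]
    prior_cost <- rows_p$total_cost[rows_p$member_id == id]
    if (prior_cost < p60) { out[i] <- "CATASTROPHIC"; next }
    toks <- strsplit(rows_t$drug_categories[i], ";", fixed = TRUE)[[1]]
    drug <- any(toks %in% drugs5)
    ratio <- if (rows_t$total_cost[i] <= 0) 0 else
      rows_t$pharmacy_cost[i] / rows_t$total_cost[i]
    u65 <- rows_b$age[rows_b$member_id == id] < 65
    if (rows_t$esrd_or_dialysis[i] || drug || ratio >= 0.6 ||
        (length(u65) == 1 && u65)) {
      out[i] <- "PERSISTENT"
    } else {
      out[i] <- "SEMI_PERSISTENT"
    }
  }
  data.frame(member_id = rows_t$member_id, group = out,
             stringsAsFactors = FALSE)
}

# random small two-year panel exercising ties and all four criteria
random_small_panel <- function(n = 40L, seed = 1L) {
  set.seed(seed)
  years <- 2016:2017
  rows <- list()
  for (i in seq_len(n)) {
    id <- sprintf("R%03d", i)
    costs <- round(sample(c(0, 100, 500, 2000, 5000, 20000, 50000), 2,
                          replace = TRUE) * runif(2, 0.9, 1.1), 2)
    if (runif(1) < 0.3) costs[2] <- costs[1]  # force cross-member ties
    phr <- runif(2) * costs
    if (runif(1) < 0.3) phr <- 0.7 * costs   # pharmacy-dominated
    drugs <- if (runif(1) < 0.2) sample(spendseg::persistent_drug_classes(), 1) else
      if (runif(1) < 0.5) "ahfs10" else ""
    age0 <- sample(c(50L, 70L), 1)
    esrd <- runif(1) < 0.1
    for (j in 1:2) {
      rows[[length(rows) + 1L]] <- member_year_row(
        id, years[j], costs[j], pharmacy_cost = round(phr[j], 2),
        age = age0 + j - 1L, esrd_or_dialysis = esrd,
        drug_categories = drugs)
    }
  }
  data.table::rbindlist(rows)
}
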