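# Rule-based classification of top-decile member-years.
#
# Evaluation order for a member in year t:
#   1. not in decile 10 of year t                -> BOTTOM90
#   2. year t-1 cost below the year t-1 P60      -> CATASTROPHIC
#   3. any persistent criterion fires            -> PERSISTENT
#        ESRD_DIALYSIS  dialysis or end-stage renal disease in year t
#        CHRONIC_DRUG   a persistent-defining chronic drug class in year t
#        PHARMACY_RATIO pharmacy cost >= 60% of total cost in year t
#        UNDER_65_2016  age < 65 at the baseline (first) panel year
#   4. otherwise                                 -> SEMI_PERSISTENT
# The precedence encodes "not already classified as catastrophic": a member
# with an acute cost shock is catastrophic even if a persistent criterion
# also fires.

#' Chronic-drug criterion flag
#'
#' `TRUE` where a member-year's `drug_categories` intersects the five
#' persistent-defining chronic drug classes (see
#' [persistent_drug_classes()]).
#'
#' @param member_year A member-year panel (or subset of rows).
#' @return Logical vector, one element per row.
#' @export
chronic_drug_flag <- function(member_year) {
  has_any_token(member_year$drug_categories, persistent_drug_classes())
}

#' Pharmacy share of total annual cost
#'
#' `pharmacy_cost / total_cost`, defined as 0 where `total_cost` is 0. The
#' persistent-group criterion fires at a ratio at or above 0.60.
#'
#' @param member_year A member-year panel (or subset of rows).
#' @return Numeric vector in `[0, 1]`, one element per row.
#' @export
pharmacy_ratio <- function(member_year) {
  ifelse(member_year$total_cost <= 0, 0,
         pmin(1, member_year$pharmacy_cost / member_year$total_cost))
}

#' Classify one year's members into spend groups
#'
#' Applies the catastrophic / persistent / semi-persistent rules to every
#' member with a decile assignment in `year`. Members outside the top decile
#' are labelled `BOTTOM90`; the three top-decile groups partition decile 10
#' exactly. Classification needs the prior year: the catastrophic rule
#' compares the year `t-1` cost against the recorded year `t-1` 60th
#' percentile (strict `<`), so the earliest panel year cannot be classified.
#'
#' The under-65 criterion is evaluated once from the member's age at the
#' baseline (first) panel year. A consequence of the rule set is that no
#' member under 65 at baseline can ever be semi-persistent.
#'
#' @param panel A member-year panel containing `year` and `year - 1` rows
#'   (and the baseline year, for ages).
#' @param assignments Decile assignments from [decile_pipeline()].
#' @param thresholds Long threshold table from [decile_pipeline()], computed
#'   on the same cohort.
#' @param year The year to classify (>= second panel year).
#' @return `data.table` with columns `member_id`, `year`, `group`,
#'   `criteria_fired` (`";"`-joined subset of `ESRD_DIALYSIS`,
#'   `CHRONIC_DRUG`, `PHARMACY_RATIO`, `UNDER_65_2016`) and
#'   `prior_year_below_p60`.
#' @export
classify_groups <- function(panel, assignments, thresholds, year) {
  panel <- as.data.table(panel)
  assignments <- as.data.table(assignments)
  thresholds <- as.data.table(thresholds)
  yr <- as.integer(year)
  py <- yr - 1L

  a_t <- assignments[assignments$year == yr]
  if (!nrow(a_t)) stop("no decile assignments for year ", yr, call. = FALSE)
  p60 <- thresholds[thresholds$year == py & thresholds$quantile_pct == 60L,
                    cost]
  if (!length(p60)) {
    stop("thresholds for prior year ", py, " are required; groups cannot be ",
         "identified in the first panel year", call. = FALSE)
  }

  rows_t <- panel[panel$year == yr]
  rows_p <- panel[panel$year == py]
  prior_cost <- rows_p$total_cost[match(a_t$member_id, rows_p$member_id)]

  base_year <- min(panel$year)
  rows_b <- panel[panel$year == base_year]
  base_age <- rows_b$age[match(a_t$member_id, rows_b$member_id)]

  top <- a_t$decile == 10L
  if (any(top & is.na(prior_cost))) {
    stop(sum(top & is.na(prior_cost)), " top-decile member(s) of year ", yr,
         " have no year ", py, " row; classify on a continuously enrolled ",
         "cohort", call. = FALSE)
  }

  ord <- match(a_t$member_id, rows_t$member_id)
  esrd <- rows_t$esrd_or_dialysis[ord]
  drug <- chronic_drug_flag(rows_t)[ord]
  phr <- pharmacy_ratio(rows_t)[ord] >= 0.60
  u65 <- !is.na(base_age) & base_age < 65L

  below <- prior_cost < p60
  crit <- tokens_from_matrix(cbind(esrd, drug, phr, u65), PERSISTENT_CRITERIA)

  group <- rep("BOTTOM90", nrow(a_t))
  group[top & below] <- "CATASTROPHIC"
  group[top & !below & (esrd | drug | phr | u65)] <- "PERSISTENT"
  group[top & !below & !(esrd | drug | phr | u65)] <- "SEMI_PERSISTENT"

  crit[!top | group == "CATASTROPHIC" | group == "SEMI_PERSISTENT"] <- ""
  data.table(member_id = a_t$member_id,
             year = yr,
             group = group,
             criteria_fired = crit,
             prior_year_below_p60 = below)
}

#' Segment every classifiable year of a panel
#'
#' Runs [decile_pipeline()] and [classify_groups()] for each panel year from
#' the second onward.
#'
#' @param panel A member-year panel (one cohort).
#' @return A list with `thresholds`, `assignments` and `groups` (row-bound
#'   [classify_groups()] output across years).
#' @export
segment_panel <- function(panel) {
  panel <- as.data.table(panel)
  dp <- decile_pipeline(panel)
  yrs <- sort(unique(panel$year))
  groups <- rbindlist(lapply(yrs[-1L], function(y) {
    classify_groups(panel, dp$assignments, dp$thresholds, y)
  }))
  list(thresholds = dp$thresholds, assignments = dp$assignments,
       groups = groups)
}
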