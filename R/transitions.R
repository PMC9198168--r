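# Year-over-year group flows with a death state, one-year mortality,
# pharmacy-spend persistence and the frailty / inpatient-cost contrast.

#' Group flow table between two classified years
#'
#' For each top-decile group of year t, tabulates where its members are one
#' year later: still in one of the top-decile groups, below the top decile
#' (`P0_60` = deciles 1-6, `P60_90` = deciles 7-9), or `DIED`. Members dying
#' during year t+1 route to `DIED` irrespective of any year t+1 spend.
#' `groups_t` must contain only members with a year t+1 state (survivors of
#' year t); a member missing from both `deaths_t1` and the year t+1
#' assignment is an error. The destination `CATASTROPHIC` column is a
#' structural zero: a top-decile origin's year-t cost is at or above the
#' year-t P90 and therefore never below the year-t P60.
#'
#' @param groups_t [classify_groups()] output for year t (top-decile rows are
#'   used; `BOTTOM90` rows are ignored).
#' @param groups_t1 [classify_groups()] output for year t+1.
#' @param assignments_t1 Decile assignments covering year t+1.
#' @param deaths_t1 Character vector of `member_id`s dying during year t+1.
#' @return A list of class `flow_table` with `year_from`, `year_to`, `counts`
#'   (3 x 6 matrix over [FLOW_DESTINATIONS]) and `row_proportions`.
#' @export
group_flows <- function(groups_t, groups_t1, assignments_t1, deaths_t1) {
  groups_t <- as.data.table(groups_t)
  groups_t1 <- as.data.table(groups_t1)
  assignments_t1 <- as.data.table(assignments_t1)
  origins <- groups_t[group %in% TOP_GROUPS]
  if (!nrow(origins)) stop("no top-decile origins in groups_t", call. = FALSE)
  y1 <- unique(groups_t1$year)
  a1 <- assignments_t1[assignments_t1$year %in% y1]

  dest_group <- groups_t1$group[match(origins$member_id, groups_t1$member_id)]
  dest_decile <- a1$decile[match(origins$member_id, a1$member_id)]
  dead <- origins$member_id %in% deaths_t1

  lab <- rep(NA_character_, nrow(origins))
  lab[dead] <- "DIED"
  in_top <- !dead & !is.na(dest_group) & dest_group %in% TOP_GROUPS
  lab[in_top] <- dest_group[in_top]
  below <- !dead & is.na(lab) & !is.na(dest_decile)
  lab[below & dest_decile <= 6L] <- "P0_60"
  lab[below & dest_decile >= 7L] <- "P60_90"
  if (anyNA(lab)) {
    stop(sum(is.na(lab)), " origin member(s) are missing from both the ",
         "deaths list and the year t+1 assignment", call. = FALSE)
  }

  counts <- table(factor(origins$group, levels = TOP_GROUPS),
                  factor(lab, levels = FLOW_DESTINATIONS))
  counts <- matrix(as.integer(counts), nrow = length(TOP_GROUPS),
                   dimnames = list(origin = TOP_GROUPS,
                                   destination = FLOW_DESTINATIONS))
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0L, 1L, rs)
  structure(list(year_from = unique(groups_t$year),
                 year_to = y1,
                 counts = counts,
                 row_proportions = props),
            class = "flow_table")
}

#' Convert a flow or transition table to long format
#'
#' @param x A `flow_table` or `transition_matrix`.
#' @return `data.table` with columns `origin`, `destination`, `count`,
#'   `proportion`.
#' @export
flows_to_long <- function(x) {
  counts <- x$counts
  props <- x$row_proportions
  data.table(origin = rep(rownames(counts), ncol(counts)),
             destination = rep(colnames(counts), each = nrow(counts)),
             count = as.integer(counts),
             proportion = as.numeric(props))
}

#' One-year mortality by spend group
#'
#' Fraction of each year-t group dying during year t+1. Computed on the same
#' origin set as [group_flows()], so the rates equal the `DIED` column of the
#' flow table exactly.
#'
#' @param groups_t [classify_groups()] output for year t, restricted to
#'   members alive at the end of year t.
#' @param deaths_t1 Character vector of `member_id`s dying during year t+1.
#' @return `data.table` with columns `group`, `deaths`, `at_risk`, `rate`.
#'   Empty groups are reported as absent (no row).
#' @export
one_year_mortality <- function(groups_t, deaths_t1) {
  groups_t <- as.data.table(groups_t)
  out <- groups_t[, .(deaths = sum(member_id %in% deaths_t1), at_risk = .N),
                  by = group]
  out[, rate := deaths / at_risk]
  setorder(out, group)
  out[]
}

#' Pharmacy-spend persistence statistics
#'
#' Among year-1 top-decile members whose pharmacy cost is at or above 60% of
#' their total cost ("high pharmacy"): the share of the top decile they
#' represent, their top-decile retention into year 2, and -- among those
#' retained -- the share whose spend stays pharmacy-dominated (ratio >= 0.6)
#' through both year 2 and year 3.
#'
#' @param panel A member-year panel.
#' @param assignments Decile assignments covering `years`.
#' @param years Three consecutive calendar years `c(y1, y2, y3)`.
#' @return A list of class `pharmacy_persistence` with `year`,
#'   `share_of_top_decile_with_high_pharmacy`, `retention_next_year`,
#'   `pharmacy_dominance_retention_two_years` and `n_high_pharmacy`.
#'   Proportions are `NA` where no qualifying members exist.
#' @export
pharmacy_persistence <- function(panel, assignments, years) {
  panel <- as.data.table(panel)
  assignments <- as.data.table(assignments)
  stopifnot(length(years) == 3L)
  if (any(diff(as.integer(years)) != 1L)) {
    stop("years must be three consecutive calendar years", call. = FALSE)
  }
  y1 <- years[1L]; y2 <- years[2L]; y3 <- years[3L]

  ratio_by_year <- function(y, ids) {
    rows <- panel[panel$year == y]
    pharmacy_ratio(rows)[match(ids, rows$member_id)]
  }
  top_ids <- function(y) {
    a <- assignments[assignments$year == y]
    a$member_id[a$decile == 10L]
  }

  d10_1 <- top_ids(y1)
  if (!length(d10_1)) stop("no top-decile members in year ", y1, call. = FALSE)
  r1 <- ratio_by_year(y1, d10_1)
  high <- !is.na(r1) & r1 >= 0.6
  share <- mean(high)
  hp <- d10_1[high]
  if (!length(hp)) {
    return(structure(list(year = y1,
                          share_of_top_decile_with_high_pharmacy = 0,
                          retention_next_year = NA_real_,
                          pharmacy_dominance_retention_two_years = NA_real_,
                          n_high_pharmacy = 0L),
                     class = "pharmacy_persistence"))
  }
  retained <- hp[hp %in% top_ids(y2)]
  retention <- length(retained) / length(hp)
  chain <- if (length(retained)) {
    r2 <- ratio_by_year(y2, retained)
    r3 <- ratio_by_year(y3, retained)
    mean(!is.na(r2) & r2 >= 0.6 & !is.na(r3) & r3 >= 0.6)
  } else NA_real_
  structure(list(year = y1,
                 share_of_top_decile_with_high_pharmacy = share,
                 retention_next_year = retention,
                 pharmacy_dominance_retention_two_years = chain,
                 n_high_pharmacy = length(hp)),
            class = "pharmacy_persistence")
}

#' Frailty contrast in inpatient cost among semi-persistent members
#'
#' Within the semi-persistent group of an index year, compares mean inpatient
#' cost between frail and non-frail members at two horizons. "Frail" means at
#' least one claims-based frailty component in both the index year and the
#' prior year; costs are measured in the index year (horizon 0) and the
#' following year (horizon 1, members with a row that year).
#'
#' @param panel A member-year panel.
#' @param groups [classify_groups()] output for the index year.
#' @param year Index year.
#' @return Named numeric `c(h0 = ..., h1 = ...)`: the ratio of frail to
#'   non-frail mean inpatient cost minus 1 at each horizon (`NA` where a
#'   stratum is empty).
#' @export
frailty_cost_contrast <- function(panel, groups, year) {
  panel <- as.data.table(panel)
  groups <- as.data.table(groups)
  yr <- as.integer(year)
  semi <- groups[group == "SEMI_PERSISTENT" & groups$year == yr, member_id]
  if (!length(semi)) {
    return(c(h0 = NA_real_, h1 = NA_real_))
  }
  nf <- function(y, ids) {
    rows <- panel[panel$year == y]
    count_tokens(rows$frailty_components)[match(ids, rows$member_id)]
  }
  f_index <- nf(yr, semi)
  f_prior <- nf(yr - 1L, semi)
  frail <- !is.na(f_index) & !is.na(f_prior) & f_index >= 1L & f_prior >= 1L
  contrast <- function(y) {
    rows <- panel[panel$year == y]
    ip <- rows$inpatient_cost[match(semi, rows$member_id)]
    mf <- mean(ip[frail & !is.na(ip)])
    mn <- mean(ip[!frail & !is.na(ip)])
    if (!is.finite(mf) || !is.finite(mn) || mn == 0) NA_real_ else mf / mn - 1
  }
  c(h0 = contrast(yr), h1 = contrast(yr + 1L))
}
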