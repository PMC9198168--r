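# Per-year cost deciles and decile-to-decile transitions.
#
# Decile membership is RANK-based, not threshold-based: members are sorted by
# (total_cost, member_id) and sliced into ten near-equal blocks, so deciles
# stay equally sized even when many members tie (e.g. at zero cost).
# Thresholds are reported alongside for interpretability and for the
# catastrophic rule's 60th-percentile comparison.

#' Per-year cost decile thresholds
#'
#' Computes the nine cost cut points (P10..P90) for one calendar year. The
#' k-th threshold is the total cost of the member at rank `ceiling(k * n /
#' 10)` when the year's members are sorted by `(total_cost, member_id)`
#' ascending.
#'
#' @param panel A member-year panel.
#' @param year Calendar year to rank.
#' @return A list of class `decile_thresholds` with elements `year`,
#'   `thresholds` (named numeric, `p10`..`p90`, non-decreasing) and `n`.
#' @export
compute_thresholds <- function(panel, year) {
  panel <- as.data.table(panel)
  yr <- as.integer(year)
  rows <- panel[panel$year == yr]
  if (nrow(rows) == 0L) stop("year ", yr, " absent from panel", call. = FALSE)
  if (nrow(rows) < 10L) {
    stop("need at least 10 members in year ", yr, " to form deciles",
         call. = FALSE)
  }
  cost_sorted <- rows$total_cost[order(rows$total_cost, rows$member_id)]
  n <- length(cost_sorted)
  th <- cost_sorted[ceiling((1:9) * n / 10)]
  structure(list(year = yr,
                 thresholds = setNames(th, paste0("p", seq(10L, 90L, 10L))),
                 n = n),
            class = "decile_thresholds")
}

#' Assign equal-frequency cost deciles for one year
#'
#' Rank-based assignment: the year's members are ordered by `(total_cost,
#' member_id)` and member at rank `r` of `n` receives decile
#' `ceiling(10 * r / n)` (10 = most expensive). Decile sizes differ by at
#' most one for any `n`, including all-ties input, and the assignment is
#' deterministic and independent of input row order.
#'
#' @param panel A member-year panel.
#' @param thresholds A [compute_thresholds()] result for the same
#'   cohort-year.
#' @return `data.table` with columns `member_id`, `year`, `decile` (1-10) and
#'   `rank_in_year` (1 = cheapest).
#' @export
assign_deciles <- function(panel, thresholds) {
  stopifnot(inherits(thresholds, "decile_thresholds"))
  panel <- as.data.table(panel)
  yr <- thresholds$year
  rows <- panel[panel$year == yr]
  if (nrow(rows) != thresholds$n) {
    stop("thresholds were computed on a different cohort-year (n = ",
         thresholds$n, ", panel year ", yr, " has ", nrow(rows), " members)",
         call. = FALSE)
  }
  n <- nrow(rows)
  o <- order(rows$total_cost, rows$member_id)
  rk <- integer(n)
  rk[o] <- seq_len(n)
  data.table(member_id = rows$member_id,
             year = yr,
             decile = as.integer(ceiling(rk * 10 / n)),
             rank_in_year = rk)
}

#' Thresholds and decile assignments for every panel year
#'
#' Convenience wrapper running [compute_thresholds()] and [assign_deciles()]
#' for each year of the panel. Thresholds must be recomputed per cohort: the
#' death-inclusive cohort has its own (higher) top-decile threshold because
#' decedents' partial-year claims enter the ranking.
#'
#' @param panel A member-year panel.
#' @return A list with `thresholds` (long `data.table`: `year`,
#'   `quantile_pct`, `cost`, `n`) and `assignments` (row-bound
#'   [assign_deciles()] output for all years).
#' @export
decile_pipeline <- function(panel) {
  panel <- as.data.table(panel)
  yrs <- sort(unique(panel$year))
  ths <- lapply(yrs, function(y) compute_thresholds(panel, y))
  assignments <- rbindlist(lapply(ths, function(t) assign_deciles(panel, t)))
  thresholds <- rbindlist(lapply(ths, function(t) {
    data.table(year = t$year, quantile_pct = seq(10L, 90L, 10L),
               cost = unname(t$thresholds), n = t$n)
  }))
  list(thresholds = thresholds, assignments = assignments)
}

#' Decile-to-decile transition matrix between two years
#'
#' Cross-tabulates members' deciles in `year_from` against `year_to`. With a
#' `deaths` vector, members of `year_from` who die during `year_to` are
#' routed to an absorbing `DIED` state irrespective of any year-to spend.
#'
#' @param assignments Long assignment table from [decile_pipeline()] (or
#'   row-bound [assign_deciles()] output) covering both years.
#' @param year_from,year_to Calendar years of the transition.
#' @param deaths Optional character vector of `member_id`s dying during
#'   `year_to`; enables the `DIED` state.
#' @return A list of class `transition_matrix` with `year_from`, `year_to`,
#'   `counts` (10 x 10 or 10 x 11 matrix) and `row_proportions` (rows sum
#'   to 1).
#' @export
decile_transitions <- function(assignments, year_from, year_to,
                               deaths = NULL) {
  assignments <- as.data.table(assignments)
  a_from <- assignments[assignments$year == year_from]
  a_to <- assignments[assignments$year == year_to]
  if (!nrow(a_from) || !nrow(a_to)) {
    stop("assignments must cover both transition years", call. = FALSE)
  }
  dest <- a_to$decile[match(a_from$member_id, a_to$member_id)]
  states <- as.character(1:10)
  lab <- as.character(dest)
  if (!is.null(deaths)) {
    lab[a_from$member_id %in% deaths] <- "DIED"
    states <- c(states, "DIED")
  }
  unresolved <- is.na(lab)
  if (any(unresolved)) {
    stop(sum(unresolved), " member(s) of year ", year_from,
         " are missing from year ", year_to,
         if (is.null(deaths)) "" else " and from the deaths list",
         "; the two years must share a cohort", call. = FALSE)
  }
  counts <- table(factor(a_from$decile, levels = 1:10),
                  factor(lab, levels = states))
  counts <- matrix(as.integer(counts), nrow = 10L,
                   dimnames = list(from = as.character(1:10), to = states))
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0L, 1L, rs)
  structure(list(year_from = year_from, year_to = year_to,
                 counts = counts, row_proportions = props),
            class = "transition_matrix")
}
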