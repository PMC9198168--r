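# Headline pipeline statistics and the generator calibration report.

#' Reference flow statistics and calibration tolerances
#'
#' The twelve headline statistics the packaged generator calibration is
#' required to reproduce when the full cohort -> decile -> segmentation ->
#' flow pipeline is run on a default-configuration panel: top-decile
#' retention, the 2017-cohort group shares, group-wise exits, retentions and
#' one-year mortality, pharmacy-spend persistence, and semi-persistent
#' frailty prevalence. `reference` values are the published estimates for a
#' large Medicare Advantage population; `tolerance` is the absolute
#' percentage-point slack allowed at the default panel size.
#'
#' @return `data.table` with columns `statistic`, `reference`, `tolerance`.
#' @export
calibration_targets <- function() {
  data.table(
    statistic = c(
      "top_decile_retention", "catastrophic_exit", "catastrophic_mortality",
      "semi_persistent_retention", "semi_persistent_exit",
      "persistent_retention", "share_catastrophic", "share_semi_persistent",
      "share_persistent", "high_pharmacy_retention", "high_pharmacy_share",
      "semi_persistent_frailty"
    ),
    reference = c(45, 80.6, 13.9, 27.8, 68.4, 57.7, 24.6, 42.7, 32.0,
                  79, 18.5, 71),
    tolerance = c(1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 2, 1.5, 2)
  )
}

#' Headline flow statistics of a member-year panel
#'
#' Runs the full pipeline on a raw generated panel and returns the twelve
#' headline statistics, all in percent. The death-exclusive cohort feeds the
#' overall top-decile retention and the pharmacy-persistence statistics; the
#' death-inclusive cohort (its own decile thresholds) feeds the group
#' shares, the group flow table with death state, and frailty prevalence.
#' Flows and mortality are computed from the second panel year to the third
#' (the first classifiable transition); members dying during the origin year
#' are counted in the group shares but have no next-year state and are
#' excluded from flow origins.
#'
#' @param panel A raw member-year panel covering at least four consecutive
#'   years (e.g. from [generate_population()]).
#' @return Named numeric vector matching
#'   `calibration_targets()$statistic`.
#' @export
headline_statistics <- function(panel) {
  panel <- as.data.table(panel)
  yrs <- sort(unique(panel$year))
  if (length(yrs) < 4L) {
    stop("panel must span at least 4 years", call. = FALSE)
  }
  y1 <- yrs[2L]; y2 <- yrs[3L]

  spec_ex <- cohort_spec(yrs[1L], yrs[length(yrs)], include_deaths = FALSE)
  spec_in <- cohort_spec(yrs[1L], yrs[length(yrs)], include_deaths = TRUE)
  ex <- filter_continuous_enrollment(panel, spec_ex)
  inc <- filter_continuous_enrollment(panel, spec_in)

  ## death-exclusive cohort: overall retention and pharmacy persistence
  dex <- decile_pipeline(ex)
  tm <- decile_transitions(dex$assignments, y1, y2)
  t_ret <- 100 * tm$row_proportions["10", "10"]
  pp <- pharmacy_persistence(ex, dex$assignments, c(y1, y2, yrs[4L]))

  ## death-inclusive cohort: groups, flows, mortality, frailty
  din <- decile_pipeline(inc)
  g1 <- classify_groups(inc, din$assignments, din$thresholds, y1)
  g2 <- classify_groups(inc, din$assignments, din$thresholds, y2)
  top1 <- g1[group %in% TOP_GROUPS]
  shares <- 100 * prop.table(table(factor(top1$group, levels = TOP_GROUPS)))

  deaths_y1 <- deaths_in_year(inc, y1)
  deaths_y2 <- deaths_in_year(inc, y2)
  origins <- top1[!member_id %in% deaths_y1]
  fl <- group_flows(origins, g2, din$assignments, deaths_y2)
  pr <- fl$row_proportions

  exit_of <- function(gname) {
    100 * sum(pr[gname, c("P0_60", "P60_90", "DIED")])
  }

  fp <- frailty_prevalence(inc, g1, y1)
  semi_any <- 100 * fp[group == "SEMI_PERSISTENT" & component == "any",
                       proportion]

  c(top_decile_retention = t_ret,
    catastrophic_exit = exit_of("CATASTROPHIC"),
    catastrophic_mortality = 100 * pr["CATASTROPHIC", "DIED"],
    semi_persistent_retention =
      100 * pr["SEMI_PERSISTENT", "SEMI_PERSISTENT"],
    semi_persistent_exit = exit_of("SEMI_PERSISTENT"),
    persistent_retention = 100 * pr["PERSISTENT", "PERSISTENT"],
    share_catastrophic = unname(shares["CATASTROPHIC"]),
    share_semi_persistent = unname(shares["SEMI_PERSISTENT"]),
    share_persistent = unname(shares["PERSISTENT"]),
    high_pharmacy_retention = 100 * pp$retention_next_year,
    high_pharmacy_share = 100 * pp$share_of_top_decile_with_high_pharmacy,
    semi_persistent_frailty = semi_any)
}

#' Members dying during a given year
#'
#' @param panel A member-year panel.
#' @param year Calendar year.
#' @return Character vector of `member_id`s with a `death_month` in `year`.
#' @export
deaths_in_year <- function(panel, year) {
  panel <- as.data.table(panel)
  yr <- as.integer(year)
  panel[panel$year == yr & !is.na(death_month), member_id]
}

#' Compare a panel's headline statistics with the calibration references
#'
#' Computes [headline_statistics()] on `panel` and compares each statistic
#' with its reference value; a row passes when the absolute difference is
#' within the stated tolerance. At the default generator configuration and
#' panel size every row is expected to pass; panels lacking the relevant
#' structure (e.g. an all-healthy population with no persistence mechanism)
#' fail the corresponding rows.
#'
#' @param panel A member-year panel spanning at least 4 years.
#' @return `data.table` with columns `statistic`, `simulated`, `reference`,
#'   `tolerance`, `pass`.
#' @export
calibration_report <- function(panel) {
  panel <- as.data.table(panel)
  if (nrow(panel) == 0L) stop("panel is empty", call. = FALSE)
  if (length(unique(panel$year)) < 3L) {
    stop("panel must span at least 3 years", call. = FALSE)
  }
  st <- headline_statistics(panel)
  tg <- calibration_targets()
  out <- data.table(statistic = tg$statistic,
                    simulated = unname(st[tg$statistic]),
                    reference = tg$reference,
                    tolerance = tg$tolerance)
  out[, pass := !is.na(simulated) &
        abs(simulated - reference) <= tolerance]
  out[]
}
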