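# Member-year panel contract and cohort construction.

#' Validate a member-year claims panel
#'
#' Checks the panel column contract and its invariants: required columns
#' present, costs non-negative, category costs summing to `total_cost` within
#' one cent, `pharmacy_cost <= total_cost`, unique `(member_id, year)` pairs,
#' `death_month` in 1-12 where present, no rows after the death year, and
#' frailty tokens drawn from the seven named components. Errors list the
#' offending rows or values.
#'
#' @param panel A member-year `data.table` (see [generate_population()] for
#'   the column contract).
#' @return `panel`, invisibly, if valid.
#' @export
validate_panel <- function(panel) {
  panel <- as.data.table(panel)
  missing_cols <- setdiff(PANEL_COLUMNS, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(panel) == 0L) stop("panel is empty", call. = FALSE)

  dup <- panel[, .N, by = .(member_id, year)][N > 1L]
  if (nrow(dup)) {
    stop("duplicate member-year rows: ",
         paste(head(sprintf("(%s, %d)", dup$member_id, dup$year), 5L),
               collapse = ", "), call. = FALSE)
  }
  costs <- c("total_cost", "pharmacy_cost", "inpatient_cost",
             "outpatient_cost", "physician_cost")
  for (cc in costs) {
    if (any(panel[[cc]] < 0, na.rm = TRUE) || anyNA(panel[[cc]])) {
      stop("negative or missing values in cost column '", cc, "'",
           call. = FALSE)
    }
  }
  gap <- abs(panel$pharmacy_cost + panel$inpatient_cost +
               panel$outpatient_cost + panel$physician_cost -
               panel$total_cost)
  if (any(gap > 0.011)) {
    bad <- which(gap > 0.011)[1L]
    stop("category costs do not sum to total_cost (first offender: member ",
         panel$member_id[bad], ", year ", panel$year[bad], ")", call. = FALSE)
  }
  if (any(panel$pharmacy_cost > panel$total_cost + 0.011)) {
    bad <- which(panel$pharmacy_cost > panel$total_cost + 0.011)[1L]
    stop("pharmacy_cost exceeds total_cost (first offender: member ",
         panel$member_id[bad], ", year ", panel$year[bad], ")", call. = FALSE)
  }
  dm <- panel$death_month
  if (any(!is.na(dm) & (dm < 1L | dm > 12L))) {
    stop("death_month outside 1-12", call. = FALSE)
  }
  died <- panel[!is.na(death_month), .(death_year = min(year)), by = member_id]
  if (nrow(died)) {
    after <- merge(panel[, .(member_id, year)], died,
                   by = "member_id")[year > death_year]
    if (nrow(after)) {
      stop("rows present after death year for member(s): ",
           paste(head(unique(after$member_id), 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  toks <- unique(unlist(split_tokens(unique(panel$frailty_components))))
  bad_toks <- setdiff(toks, frailty_component_names())
  if (length(bad_toks)) {
    stop("unknown frailty components: ", paste(bad_toks, collapse = ", "),
         call. = FALSE)
  }
  invisible(panel)
}

#' Cohort construction specification
#'
#' @param first_year,last_year Calendar-year window of the cohort.
#' @param include_deaths If `FALSE` (the default) the cohort keeps only
#'   members enrolled all 12 months of every window year and alive through
#'   the window; if `TRUE` it additionally keeps members who die within the
#'   window and were continuously enrolled up to and including the month of
#'   death.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(first_year, last_year, include_deaths = FALSE) {
  if (last_year < first_year) stop("empty cohort window", call. = FALSE)
  structure(list(first_year = as.integer(first_year),
                 last_year = as.integer(last_year),
                 include_deaths = isTRUE(include_deaths)),
            class = "cohort_spec")
}

# canonicalize an enrolled_months token string column (sorted, ";"-joined)
canonical_months <- function(x) {
  canon <- c(month_prefix_strings(),
             vapply(1:12, function(m) paste(setdiff(1:12, m), collapse = ";"),
                    character(1)))
  ok <- x %in% canon | x == ""
  if (all(ok)) return(x)
  y <- x
  y[!ok] <- vapply(split_tokens(x[!ok]), function(m) {
    paste(sort(unique(as.integer(m))), collapse = ";")
  }, character(1))
  y
}

#' Filter a panel to a continuously enrolled cohort
#'
#' Implements the two cohort constructions used throughout the package. A
#' "gap" is any calendar month of a window year with no enrollment; partial
#' months count as enrolled. In the death-exclusive cohort
#' (`include_deaths = FALSE`) a member must be enrolled all 12 months of
#' every window year with no death; the death-inclusive cohort additionally
#' retains members dying inside the window who were enrolled every month up
#' to and including the death month. The death-inclusive cohort is always a
#' superset of the death-exclusive one, and filtering is idempotent.
#'
#' Death-year rows keep their observed partial-year claims with no
#' annualization: spending is time-dependent within the year, so weighting a
#' partial year up would distort the cost distribution. This biases deciles
#' computed on the inclusive cohort and is a documented limitation.
#'
#' @param panel A member-year panel.
#' @param spec A [cohort_spec()].
#' @return The filtered panel (rows restricted to the window and to
#'   qualifying members).
#' @export
filter_continuous_enrollment <- function(panel, spec) {
  panel <- as.data.table(panel)
  stopifnot(inherits(spec, "cohort_spec"))
  yrs <- spec$first_year:spec$last_year
  if (!all(yrs %in% unique(panel$year))) {
    stop("cohort window ", spec$first_year, "-", spec$last_year,
         " extends outside the panel years", call. = FALSE)
  }
  win <- panel[year %in% yrs]
  win[, enrolled_months := canonical_months(enrolled_months)]
  full12 <- month_prefix_strings()[12L]
  prefix <- month_prefix_strings()

  info <- win[, .(
    n_years = .N,
    first = min(year),
    all_full = all(enrolled_months == full12),
    death_year = {
      dy <- year[!is.na(death_month)]
      if (length(dy)) dy[1L] else NA_integer_
    },
    death_ok = {
      dm <- death_month[!is.na(death_month)]
      dy <- year[!is.na(death_month)]
      length(dm) <= 1L &&
        (length(dm) == 0L ||
           (enrolled_months[year == dy] == prefix[dm] &&
              all(enrolled_months[year < dy] == full12)))
    }
  ), by = member_id]

  survivors <- info[is.na(death_year) & first == yrs[1L] &
                      n_years == length(yrs) & all_full == TRUE, member_id]
  keep <- survivors
  if (spec$include_deaths) {
    dec <- info[!is.na(death_year) & first == yrs[1L] & death_ok == TRUE &
                  n_years == death_year - yrs[1L] + 1L, member_id]
    keep <- c(survivors, dec)
  }
  out <- win[member_id %in% keep]
  setorder(out, member_id, year)
  out[]
}

#' Read or write a member-year panel CSV
#'
#' The CSV columns follow the member-year contract exactly; set-valued fields
#' are `";"`-delimited token strings and an absent `death_month` is an empty
#' field. `read_panel()` validates on read (see [validate_panel()]) and
#' `write_panel()` / `read_panel()` round-trip losslessly.
#'
#' @param path CSV file path.
#' @param panel A member-year panel.
#' @return `read_panel()` returns a validated `data.table`; `write_panel()`
#'   returns `path` invisibly.
#' @export
read_panel <- function(path) {
  panel <- fread(path,
                 colClasses = list(
                   character = c("member_id", "sex", "race", "geography",
                                 "enrolled_months", "chronic_conditions",
                                 "frailty_components", "drug_categories",
                                 "procedure_categories"),
                   integer = c("year", "hospital_days", "death_month", "age",
                               "distinct_providers", "distinct_specialties"),
                   numeric = c("total_cost", "pharmacy_cost", "inpatient_cost",
                               "outpatient_cost", "physician_cost",
                               "ses_index"),
                   logical = c("dual_eligible", "esrd_or_dialysis")))
  for (cc in c("enrolled_months", "chronic_conditions", "frailty_components",
               "drug_categories", "procedure_categories")) {
    set(panel, which(is.na(panel[[cc]])), cc, "")
  }
  panel[, enrolled_months := canonical_months(enrolled_months)]
  validate_panel(panel)
  panel[]
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  fwrite(as.data.table(panel), path, na = "")
  invisible(path)
}
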