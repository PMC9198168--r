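# Group characteristics tables, significance tests and frailty prevalence.

CONTINUOUS_CHARACTERISTICS <- c(
  "age", "ses_index", "n_frailty_components", "n_chronic_conditions",
  "n_procedure_categories", "hospital_days", "distinct_providers",
  "distinct_specialties", "n_drug_categories"
)
CATEGORICAL_CHARACTERISTICS <- c(
  "sex", "age_band", "race", "geography", "dual_eligible"
)

# derive the characteristic columns used by reporting from raw panel rows
characteristic_frame <- function(rows) {
  dt <- data.table(
    member_id = rows$member_id,
    sex = rows$sex,
    age = as.numeric(rows$age),
    age_band = cut(rows$age, c(-Inf, 64, 75, Inf),
                   labels = c("<65", "65-75", ">75")),
    ses_index = rows$ses_index,
    race = factor(rows$race, levels = RACE_LEVELS),
    geography = factor(rows$geography, levels = GEO_LEVELS),
    dual_eligible = ifelse(rows$dual_eligible, "yes", "no"),
    n_frailty_components = as.numeric(count_tokens(rows$frailty_components)),
    n_chronic_conditions = as.numeric(count_tokens(rows$chronic_conditions)),
    n_procedure_categories =
      as.numeric(count_tokens(rows$procedure_categories)),
    n_drug_categories = as.numeric(count_tokens(rows$drug_categories)),
    hospital_days = as.numeric(rows$hospital_days),
    distinct_providers = as.numeric(rows$distinct_providers),
    distinct_specialties = as.numeric(rows$distinct_specialties)
  )
  dt
}

#' Group characteristics table for one classified year
#'
#' Demographics and healthcare-utilization summaries per spend group
#' (columns Bottom 90% / Catastrophic / Persistent / Semi-persistent):
#' means with standard errors (`SD / sqrt(n)`) for continuous
#' characteristics, within-characteristic percentages for categorical ones.
#' Percentages are reported without standard errors.
#'
#' @param panel A member-year panel.
#' @param groups [classify_groups()] output covering `year`.
#' @param year The classified year to summarize.
#' @return Long `data.table` with columns `group`, `characteristic`, `level`
#'   (`NA` for continuous rows), `value`, `se` (`NA` for categorical rows)
#'   and `n_group`.
#' @export
characteristics_table <- function(panel, groups, year) {
  panel <- as.data.table(panel)
  groups <- as.data.table(groups)
  yr <- as.integer(year)
  g <- groups[groups$year == yr]
  if (!nrow(g)) stop("year ", yr, " has not been classified", call. = FALSE)
  rows <- panel[panel$year == yr]
  cf <- characteristic_frame(rows)
  cf[, group := g$group[match(cf$member_id, g$member_id)]]
  cf <- cf[!is.na(group)]
  sizes <- cf[, .N, by = group]

  cont <- rbindlist(lapply(CONTINUOUS_CHARACTERISTICS, function(ch) {
    cf[, .(characteristic = ch, level = NA_character_,
           value = mean(.SD[[1L]]),
           se = sd(.SD[[1L]]) / sqrt(.N)),
       by = group, .SDcols = ch]
  }))
  cat_ <- rbindlist(lapply(CATEGORICAL_CHARACTERISTICS, function(ch) {
    tmp <- data.table(group = cf$group, level = as.character(cf[[ch]]))
    tab <- tmp[, .(n = .N), by = .(group, level)]
    tab[, .(characteristic = ch, level = level,
            value = 100 * n / sum(n), se = NA_real_), by = group]
  }))
  out <- rbind(cont, cat_, use.names = TRUE)
  out[, n_group := sizes$N[match(out$group, sizes$group)]]
  setcolorder(out, c("group", "characteristic", "level", "value", "se",
                     "n_group"))
  setorder(out, characteristic, group, level, na.last = TRUE)
  out[]
}

#' Omnibus and pairwise group comparison for one characteristic
#'
#' Chi-square test of independence (no continuity correction) for
#' categorical characteristics, one-way ANOVA for continuous ones, each
#' followed by the corresponding pairwise tests (chi-square on the 2 x K
#' subtable, or Welch two-sample t). Pairwise p-values are reported
#' unadjusted.
#'
#' @param panel A member-year panel.
#' @param groups [classify_groups()] output for one year.
#' @param characteristic One of the reporting characteristics (see
#'   [characteristics_table()]); continuous panel columns are also accepted.
#' @return A list with `test_name`, `statistic`, `p_value` and `pairwise`
#'   (`data.table` of group pairs).
#' @export
group_tests <- function(panel, groups, characteristic) {
  panel <- as.data.table(panel)
  groups <- as.data.table(groups)
  yr <- unique(groups$year)
  stopifnot(length(yr) == 1L)
  rows <- panel[panel$year == yr]
  cf <- characteristic_frame(rows)
  cf[, group := groups$group[match(cf$member_id, groups$member_id)]]
  cf <- cf[!is.na(group)]
  if (!characteristic %in% names(cf)) {
    stop("unknown characteristic: ", characteristic, call. = FALSE)
  }
  x <- cf[[characteristic]]
  grp <- factor(cf$group)
  present <- levels(grp)[table(grp) >= 2L]
  if (length(present) < 2L) {
    stop("need at least two groups with at least two members", call. = FALSE)
  }
  pairs <- utils::combn(present, 2L)

  if (characteristic %in% CONTINUOUS_CHARACTERISTICS) {
    fit <- aov(x ~ grp)
    an <- summary(fit)[[1L]]
    pw <- rbindlist(apply(pairs, 2L, function(p) {
      tt <- t.test(x[grp == p[1L]], x[grp == p[2L]])
      data.table(group1 = p[1L], group2 = p[2L],
                 statistic = unname(tt$statistic), p_value = tt$p.value)
    }))
    list(test_name = "anova",
         statistic = an[["F value"]][1L],
         p_value = an[["Pr(>F)"]][1L],
         pairwise = pw)
  } else {
    tab <- table(grp, droplevels(factor(x)))
    if (any(dim(tab) < 2L)) {
      stop("degenerate contingency table for '", characteristic, "'",
           call. = FALSE)
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    pw <- rbindlist(apply(pairs, 2L, function(p) {
      sub <- tab[p, , drop = FALSE]
      sub <- sub[, colSums(sub) > 0L, drop = FALSE]
      cp <- suppressWarnings(chisq.test(sub, correct = FALSE))
      data.table(group1 = p[1L], group2 = p[2L],
                 statistic = unname(cp$statistic), p_value = cp$p.value)
    }))
    list(test_name = "chi-square",
         statistic = unname(ct$statistic),
         p_value = ct$p.value,
         pairwise = pw)
  }
}

#' Frailty-component prevalence by spend group
#'
#' Proportion of each group's members carrying each of the seven
#' claims-based frailty components in `year`, plus the share with at least
#' one component.
#'
#' @param panel A member-year panel.
#' @param groups [classify_groups()] output covering `year`.
#' @param year The classified year.
#' @return Long `data.table` with columns `group`, `component` (the seven
#'   component names plus `"any"`) and `proportion`.
#' @export
frailty_prevalence <- function(panel, groups, year) {
  panel <- as.data.table(panel)
  groups <- as.data.table(groups)
  yr <- as.integer(year)
  g <- groups[groups$year == yr]
  rows <- panel[panel$year == yr]
  fr <- rows$frailty_components[match(g$member_id, rows$member_id)]
  comps <- frailty_component_names()
  rbindlist(lapply(split(seq_len(nrow(g)), g$group), function(idx) {
    x <- fr[idx]
    data.table(group = g$group[idx[1L]],
               component = c(comps, "any"),
               proportion = c(vapply(comps, function(cmp) {
                 mean(has_any_token(x, cmp))
               }, numeric(1)),
               mean(count_tokens(x) >= 1L)))
  }))
}
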