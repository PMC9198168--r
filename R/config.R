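# Generator configuration: a nested list describing a mixture of latent
# member archetypes. The archetypes are a modelling device only -- the
# downstream segmentation never sees them; catastrophic / persistent /
# semi-persistent membership must emerge from simulated costs and flags.

ARCHETYPE_NAMES <- c("HEALTHY", "FLUCTUATING_CHRONIC", "MED_DEPENDENT",
                     "EVENT_PRONE", "FRAIL_COMPLEX")

archetype_spec <- function(cost, pharmacy, event, death, flags, frailty,
                           conditions, drugs, procedures, utilization,
                           demographics) {
  list(cost = cost, pharmacy = pharmacy, event = event, death = death,
       flags = flags, frailty = frailty, conditions = conditions,
       drugs = drugs, procedures = procedures, utilization = utilization,
       demographics = demographics)
}

#' Default synthetic-claims generator configuration
#'
#' Returns the packaged calibration of the synthetic member-year claims
#' generator. The population is a mixture of five latent archetypes
#' (`HEALTHY`, `FLUCTUATING_CHRONIC`, `MED_DEPENDENT`, `EVENT_PRONE`,
#' `FRAIL_COMPLEX`), each with its own annual log-cost location and scale,
#' member-level and year-level variance components with AR(1) persistence,
#' pharmacy-share distribution, catastrophic-event process, death hazard, and
#' prevalence vectors for chronic-condition, frailty, drug-class and
#' procedure-category flags. The defaults were tuned once, offline, so that
#' the full cohort -> decile -> segmentation -> flow pipeline applied to a
#' generated panel reproduces the headline year-over-year flow, mortality,
#' pharmacy-persistence and frailty statistics that motivate the package (see
#' [calibration_report()] and the package vignette); they are not meant to be
#' re-tuned at run time.
#'
#' The dollar scale of simulated costs is arbitrary: segmentation operates on
#' within-year cost ranks and cost ratios, never on absolute dollars.
#'
#' @return A nested list of class `spendseg_config` with elements
#'   `version`, `n_members`, `years`, `gap_probability`, `archetype_mix`, and
#'   per-archetype parameter blocks under `archetypes`.
#' @seealso [generate_population()], [validate_config()],
#'   [calibration_report()]
#' @examples
#' cfg <- default_config()
#' sum(cfg$archetype_mix)
#' @export
default_config <- function() {
  cfg <- list(
    version = "1.0",
    n_members = 150000L,
    years = 2016:2019,
    # small fraction of members with a one-month enrollment gap, so the
    # continuous-enrollment filter has work to do
    gap_probability = 0.03,
    archetype_mix = c(
      HEALTHY = 0.357,
      FLUCTUATING_CHRONIC = 0.20,
      MED_DEPENDENT = 0.121,
      EVENT_PRONE = 0.195,
      FRAIL_COMPLEX = 0.127
    ),
    archetypes = list(
      HEALTHY = archetype_spec(
        cost = list(meanlog = 7.0, sd_member = 1.05, sd_year = 0.78,
                    ar1 = 0.66, medical_split = c(0.18, 0.47, 0.35),
                    split_concentration = 8,
                    inpatient_frailty_tilt = 0.7),
        pharmacy = list(mean_logit = -1.10, severity_slope = 0.15,
                        member_sd = 0.55, concentration = 40),
        event = list(prob = 0.010, meanlog = 9.6, sdlog = 0.7,
                     aftermath = 0.10,
                     frailty_tilt = 0.7),
        death = list(intercept = -4.60, severity_slope = 0.70,
                     event_boost = 1.2, post_event_boost = 0.6, post_event_decay = 0.5,
                     eol_cost_mult = 1.6),
        flags = list(esrd = 0.002, under65 = 0.100, dual_eligible = 0.07),
        frailty = list(base = c(0.06, 0.08, 0.05, 0.02, 0.02, 0.03, 0.03),
                       member_sd = 0.8, severity_corr = 0.30),
        conditions = list(logit_shift = -0.60, severity_slope = 0.45),
        drugs = list(persistent_class_probs =
                       c(antineoplastic = 0.006, dmard = 0.004,
                         phosphate_removing = 0.001, immunomodulatory = 0.004,
                         hiv_nrti = 0.002),
                     background_shift = 0.0, severity_slope = 0.30,
                     annual_incidence = 0.010),
        procedures = list(logit_shift = -0.40, severity_slope = 0.35),
        utilization = list(hospital_day_cost = 2600, providers_mean = 7,
                           specialties_mean = 4.5),
        demographics = list(female = 0.58, ses_mean = 52.5, ses_sd = 8,
                            race = c(0.018, 0.125, 0.016, 0.002, 0.020,
                                     0.801, 0.018),
                            geography = c(0.32, 0.39, 0.286, 0.004))
      ),
      FLUCTUATING_CHRONIC = archetype_spec(
        cost = list(meanlog = 8.28, sd_member = 0.66, sd_year = 1.10,
                    ar1 = 0.29, medical_split = c(0.30, 0.42, 0.28),
                    split_concentration = 6,
                    inpatient_frailty_tilt = 0.7),
        pharmacy = list(mean_logit = -0.95, severity_slope = 0.10,
                        member_sd = 0.50, concentration = 40),
        event = list(prob = 0.030, meanlog = 10.0, sdlog = 0.7,
                     aftermath = 0.15,
                     frailty_tilt = 0.7),
        death = list(intercept = -3.10, severity_slope = 0.50,
                     event_boost = 1.0, post_event_boost = 0.4, post_event_decay = 0.5,
                     eol_cost_mult = 1.8),
        flags = list(esrd = 0.004, under65 = 0.090, dual_eligible = 0.10),
        frailty = list(base = c(0.22, 0.19, 0.17, 0.11, 0.08, 0.10, 0.08),
                       member_sd = 0.9, severity_corr = 0.35),
        conditions = list(logit_shift = 0.45, severity_slope = 0.40),
        drugs = list(persistent_class_probs =
                       c(antineoplastic = 0.010, dmard = 0.008,
                         phosphate_removing = 0.002, immunomodulatory = 0.008,
                         hiv_nrti = 0.002),
                     background_shift = 0.65, severity_slope = 0.25,
                     annual_incidence = 0.115),
        procedures = list(logit_shift = 0.45, severity_slope = 0.30),
        utilization = list(hospital_day_cost = 2600, providers_mean = 14,
                           specialties_mean = 8),
        demographics = list(female = 0.59, ses_mean = 52.4, ses_sd = 8,
                            race = c(0.012, 0.130, 0.012, 0.002, 0.016,
                                     0.814, 0.014),
                            geography = c(0.34, 0.39, 0.266, 0.004))
      ),
      MED_DEPENDENT = archetype_spec(
        cost = list(meanlog = 9.15, sd_member = 0.90, sd_year = 0.55,
                    ar1 = 0.735, medical_split = c(0.22, 0.45, 0.33),
                    split_concentration = 6,
                    inpatient_frailty_tilt = 0.7),
        pharmacy = list(mean_logit = 0.42, severity_slope = 0.36,
                        member_sd = 0.60, concentration = 60),
        event = list(prob = 0.020, meanlog = 10.0, sdlog = 0.7,
                     aftermath = 0.10,
                     frailty_tilt = 0.7),
        death = list(intercept = -3.15, severity_slope = 0.50,
                     event_boost = 1.0, post_event_boost = 0.7, post_event_decay = 0.5,
                     eol_cost_mult = 1.8),
        flags = list(esrd = 0.070, under65 = 0.450, dual_eligible = 0.26),
        frailty = list(base = c(0.12, 0.14, 0.09, 0.05, 0.04, 0.06, 0.05),
                       member_sd = 0.9, severity_corr = 0.30),
        conditions = list(logit_shift = 0.55, severity_slope = 0.35),
        drugs = list(persistent_class_probs =
                       c(antineoplastic = 0.28, dmard = 0.20,
                         phosphate_removing = 0.06, immunomodulatory = 0.24,
                         hiv_nrti = 0.12),
                     background_shift = 1.10, severity_slope = 0.25,
                     annual_incidence = 0.040),
        procedures = list(logit_shift = 0.30, severity_slope = 0.30),
        utilization = list(hospital_day_cost = 2600, providers_mean = 12,
                           specialties_mean = 7),
        demographics = list(female = 0.53, ses_mean = 52.2, ses_sd = 8,
                            race = c(0.009, 0.225, 0.018, 0.003, 0.013,
                                     0.719, 0.013),
                            geography = c(0.38, 0.37, 0.246, 0.004))
      ),
      EVENT_PRONE = archetype_spec(
        cost = list(meanlog = 7.30, sd_member = 0.80, sd_year = 0.80,
                    ar1 = 0.45, medical_split = c(0.22, 0.45, 0.33),
                    split_concentration = 8,
                    inpatient_frailty_tilt = 0.7),
        pharmacy = list(mean_logit = -1.00, severity_slope = 0.15,
                        member_sd = 0.55, concentration = 40),
        event = list(prob = 0.146, meanlog = 10.65, sdlog = 0.75,
                     aftermath = 0.175,
                     frailty_tilt = 0.7),
        death = list(intercept = -4.45, severity_slope = 0.60,
                     event_boost = 1.0, post_event_boost = 2.55, post_event_decay = 0.80,
                     eol_cost_mult = 1.7),
        flags = list(esrd = 0.003, under65 = 0.090, dual_eligible = 0.09),
        frailty = list(base = c(0.12, 0.10, 0.08, 0.05, 0.04, 0.05, 0.05),
                       member_sd = 0.8, severity_corr = 0.30),
        conditions = list(logit_shift = -0.10, severity_slope = 0.40),
        drugs = list(persistent_class_probs =
                       c(antineoplastic = 0.008, dmard = 0.005,
                         phosphate_removing = 0.001, immunomodulatory = 0.005,
                         hiv_nrti = 0.002),
                     background_shift = 0.25, severity_slope = 0.25,
                     annual_incidence = 0.015),
        procedures = list(logit_shift = 0.00, severity_slope = 0.40),
        utilization = list(hospital_day_cost = 2600, providers_mean = 10,
                           specialties_mean = 6),
        demographics = list(female = 0.53, ses_mean = 52.6, ses_sd = 8,
                            race = c(0.012, 0.125, 0.023, 0.002, 0.017,
                                     0.805, 0.016),
                            geography = c(0.295, 0.375, 0.326, 0.004))
      ),
      FRAIL_COMPLEX = archetype_spec(
        cost = list(meanlog = 8.75, sd_member = 0.76, sd_year = 1.10,
                    ar1 = 0.335, medical_split = c(0.34, 0.39, 0.27),
                    split_concentration = 6,
                    inpatient_frailty_tilt = 0.7),
        pharmacy = list(mean_logit = -1.10, severity_slope = 0.10,
                        member_sd = 0.50, concentration = 40),
        event = list(prob = 0.050, meanlog = 10.0, sdlog = 0.7,
                     aftermath = 0.15,
                     frailty_tilt = 0.7),
        death = list(intercept = -2.25, severity_slope = 0.45,
                     event_boost = 0.8, post_event_boost = 0.2, post_event_decay = 0.5,
                     eol_cost_mult = 2.0),
        flags = list(esrd = 0.006, under65 = 0.070, dual_eligible = 0.14),
        frailty = list(base = c(0.40, 0.36, 0.32, 0.24, 0.17, 0.20, 0.15),
                       member_sd = 1.0, severity_corr = 0.40),
        conditions = list(logit_shift = 0.95, severity_slope = 0.35),
        drugs = list(persistent_class_probs =
                       c(antineoplastic = 0.010, dmard = 0.008,
                         phosphate_removing = 0.002, immunomodulatory = 0.008,
                         hiv_nrti = 0.001),
                     background_shift = 0.85, severity_slope = 0.25,
                     annual_incidence = 0.115),
        procedures = list(logit_shift = 0.75, severity_slope = 0.30),
        utilization = list(hospital_day_cost = 2600, providers_mean = 17,
                           specialties_mean = 9),
        demographics = list(female = 0.59, ses_mean = 52.5, ses_sd = 8,
                            race = c(0.009, 0.128, 0.009, 0.002, 0.013,
                                     0.827, 0.012),
                            geography = c(0.344, 0.393, 0.259, 0.004))
      )
    )
  )
  structure(cfg, class = c("spendseg_config", "list"))
}

#' Validate a generator configuration
#'
#' Checks structural invariants of a [default_config()]-shaped configuration:
#' the archetype mix sums to one, probabilities lie in `[0, 1]`, scale
#' parameters are positive and the simulated years are consecutive. Errors
#' name the offending field.
#'
#' @param config A `spendseg_config` list.
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  fail <- function(field, msg) {
    stop("invalid generator config: field '", field, "' ", msg, call. = FALSE)
  }
  for (f in c("n_members", "years", "archetype_mix", "archetypes",
              "gap_probability")) {
    if (is.null(config[[f]])) fail(f, "is missing")
  }
  mix <- config$archetype_mix
  if (!setequal(names(mix), ARCHETYPE_NAMES)) {
    fail("archetype_mix", "must be named by the five archetypes")
  }
  if (abs(sum(mix) - 1) > 1e-9) fail("archetype_mix", "must sum to 1")
  if (any(mix < 0)) fail("archetype_mix", "has negative proportions")
  yrs <- config$years
  if (length(yrs) < 2L || any(diff(yrs) != 1L)) {
    fail("years", "must be at least two consecutive calendar years")
  }
  if (config$n_members < 1) fail("n_members", "must be a positive count")
  if (config$gap_probability < 0 || config$gap_probability > 1) {
    fail("gap_probability", "must be a probability in [0, 1]")
  }
  chk_prob <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
      fail(field, "must be a probability in [0, 1]")
    }
  }
  chk_pos <- function(x, field) {
    if (any(!is.finite(x)) || any(x <= 0)) fail(field, "must be positive")
  }
  for (a in ARCHETYPE_NAMES) {
    ar <- config$archetypes[[a]]
    if (is.null(ar)) fail(paste0("archetypes$", a), "is missing")
    p <- function(sub) paste0("archetypes$", a, "$", sub)
    chk_pos(ar$cost$sd_member, p("cost$sd_member"))
    chk_pos(ar$cost$sd_year, p("cost$sd_year"))
    if (abs(ar$cost$ar1) >= 1) fail(p("cost$ar1"), "must lie in (-1, 1)")
    if (length(ar$cost$medical_split) != 3L || any(ar$cost$medical_split <= 0)) {
      fail(p("cost$medical_split"), "must be 3 positive proportions")
    }
    chk_pos(ar$pharmacy$concentration, p("pharmacy$concentration"))
    chk_prob(ar$event$prob, p("event$prob"))
    chk_pos(ar$event$sdlog, p("event$sdlog"))
    if (is.null(ar$event$aftermath) || ar$event$aftermath < 0) {
      fail(p("event$aftermath"), "must be a non-negative fraction")
    }
    chk_pos(ar$death$eol_cost_mult, p("death$eol_cost_mult"))
    chk_prob(unlist(ar$flags), p("flags"))
    if (length(ar$frailty$base) != 7L) {
      fail(p("frailty$base"), "must have 7 component prevalences")
    }
    chk_prob(ar$frailty$base, p("frailty$base"))
    chk_prob(ar$drugs$persistent_class_probs,
             p("drugs$persistent_class_probs"))
    chk_prob(ar$drugs$annual_incidence %||% 0, p("drugs$annual_incidence"))
    chk_prob(ar$demographics$female, p("demographics$female"))
    if (length(ar$demographics$race) != length(RACE_LEVELS)) {
      fail(p("demographics$race"), "must have one probability per race level")
    }
    chk_prob(ar$demographics$race, p("demographics$race"))
    if (length(ar$demographics$geography) != length(GEO_LEVELS)) {
      fail(p("demographics$geography"),
           "must have one probability per geography level")
    }
    chk_prob(ar$demographics$geography, p("demographics$geography"))
  }
  invisible(config)
}

#' Read or write a generator configuration as YAML
#'
#' Round-trips a `spendseg_config` through a nested key/value text file.
#'
#' @param path File path.
#' @param config A `spendseg_config` list.
#' @return `read_config()` returns the validated configuration;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$years <- as.integer(cfg$years)
  cfg$n_members <- as.integer(cfg$n_members)
  cfg$archetype_mix <- unlist(cfg$archetype_mix)
  for (a in names(cfg$archetypes)) {
    for (blk in c("cost", "pharmacy", "event", "death", "flags", "frailty",
                  "conditions", "drugs", "procedures", "utilization",
                  "demographics")) {
      b <- cfg$archetypes[[a]][[blk]]
      cfg$archetypes[[a]][[blk]] <- lapply(b, function(x) {
        if (is.list(x)) unlist(x) else x
      })
    }
  }
  cfg <- structure(cfg, class = c("spendseg_config", "list"))
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  cfg <- unclass(config)
  # named numeric vectors must become maps, not bare sequences
  cfg$archetype_mix <- as.list(cfg$archetype_mix)
  for (a in names(cfg$archetypes)) {
    cfg$archetypes[[a]]$drugs$persistent_class_probs <-
      as.list(cfg$archetypes[[a]]$drugs$persistent_class_probs)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
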