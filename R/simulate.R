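# Synthetic longitudinal claims generator.
#
# Annual total cost for member i of archetype a in year t is lognormal:
#   log C_it = mu_a + tau_a * s_i + sigma_a * u_it  (+ event spike)
# with s_i a member-level severity intercept and u_it a standard-normal AR(1)
# process (coefficient rho_a), so costs are heavy-tailed with year-to-year
# persistence. Catastrophic events add an independent lognormal inpatient
# spike. Death fires annually from a logistic hazard in the member's current
# severity z-score, with boosts during and after an event year; the death
# month is uniform within the year and the death-year claims are partial.

#' Generate a synthetic member-year claims panel
#'
#' Simulates `n_members` members over `config$years`, one row per member per
#' calendar year up to and including the death year. Members are drawn from
#' the latent archetype mixture of `config`; all downstream structure
#' (top-decile membership, group classification, flows) emerges from the
#' simulated costs and category-level flags, never from the latent label,
#' which is deliberately not emitted.
#'
#' @param config A [default_config()]-shaped generator configuration.
#' @param seed Integer seed; identical `(config, seed)` give bit-identical
#'   panels.
#' @param n_members Optional override of `config$n_members`.
#' @return A `data.table` with one row per member-year and the columns listed
#'   under [validate_panel()]. Set-valued fields (`chronic_conditions`,
#'   `frailty_components`, `drug_categories`, `procedure_categories`,
#'   `enrolled_months`) are `";"`-delimited token strings.
#' @examples
#' cfg <- default_config()
#' panel <- generate_population(cfg, seed = 1, n_members = 500)
#' panel[, .N, by = year]
#' @export
generate_population <- function(config = default_config(), seed = 1L,
                                n_members = NULL) {
  validate_config(config)
  stopifnot(length(seed) == 1L, is.finite(seed))
  n <- as.integer(n_members %||% config$n_members)
  if (is.na(n) || n < 1L) {
    stop("invalid generator config: field 'n_members' must be a positive count")
  }
  years <- as.integer(config$years)
  ny <- length(years)
  set.seed(as.integer(seed))

  A <- config$archetypes
  arch <- sample(ARCHETYPE_NAMES, n, replace = TRUE,
                 prob = config$archetype_mix[ARCHETYPE_NAMES])
  ai <- match(arch, ARCHETYPE_NAMES)

  # per-member scalar parameter lookup: config path -> vector of length n
  pull <- function(...) {
    keys <- list(...)
    v <- vapply(A, function(a) as.numeric(Reduce(`[[`, keys, a)), numeric(1))
    v[ai]
  }
  # per-archetype vector parameter -> K x len matrix
  pullm <- function(...) {
    keys <- list(...)
    do.call(rbind, lapply(A, function(a) as.numeric(Reduce(`[[`, keys, a))))
  }

  member_id <- sprintf("M%07d", seq_len(n))

  ## ---- member-level draws -------------------------------------------------
  s <- rnorm(n)  # severity intercept (log-cost units via tau)

  mu <- pull("cost", "meanlog")
  tau <- pull("cost", "sd_member")
  sig <- pull("cost", "sd_year")
  rho <- pull("cost", "ar1")
  zden <- sqrt(tau^2 + sig^2)

  under65 <- runif(n) < pull("flags", "under65")
  age0 <- ifelse(under65,
                 40L + as.integer(floor(runif(n, 0, 25))),
                 65L + pmin(34L, as.integer(floor(rgamma(n, 2.0, scale = 4.2)))))
  sex <- ifelse(runif(n) < pull("demographics", "female"), "F", "M")
  dual <- runif(n) < pull("flags", "dual_eligible")
  esrd <- runif(n) < pull("flags", "esrd")
  ses <- round(rnorm(n, pull("demographics", "ses_mean"),
                     pull("demographics", "ses_sd")), 1)
  race <- sample_categorical(pullm("demographics", "race")[ai, , drop = FALSE],
                             RACE_LEVELS)
  geography <- sample_categorical(
    pullm("demographics", "geography")[ai, , drop = FALSE], GEO_LEVELS)

  # chronic drug classes, member-level (chronic therapy persists across years)
  p5 <- pullm("drugs", "persistent_class_probs")[ai, , drop = FALSE]
  drug5 <- matrix(runif(n * 5L), n, 5L) < p5
  bg_base <- 0.40 * 0.82^(seq_along(BACKGROUND_DRUG_CLASSES) - 1L)
  bg_shift <- pull("drugs", "background_shift") +
    pull("drugs", "severity_slope") * s
  Qbg <- matrix(qlogis(bg_base), n, length(bg_base), byrow = TRUE)
  drugbg <- matrix(runif(n * length(bg_base)), n) < plogis(Qbg + bg_shift)
  drug_tokens <- tokens_from_matrix(
    cbind(drug5, drugbg), c(persistent_drug_classes(), BACKGROUND_DRUG_CLASSES))

  # chronic-drug onset: members can newly start one of the five
  # persistent-defining therapies in a later year (new cancer diagnosis,
  # dialysis initiation, ...); the flag persists from the onset year on
  inc_p <- pull("drugs", "annual_incidence")
  onset_year_idx <- 2L + as.integer(floor(log(runif(n)) / log(1 - pmin(0.999, inc_p))))
  onset_year_idx[inc_p <= 0] <- ny + 1L
  class_w <- p5 + 1e-6
  onset_class <- persistent_drug_classes()[max.col(log(matrix(runif(n * 5L), n, 5L)) / class_w)]
  has_onset_class <- vapply(seq_len(n), function(i) {
    grepl(paste0("(^|;)", onset_class[i], "(;|$)"), drug_tokens[i])
  }, logical(1))
  drug_tokens_onset <- ifelse(
    has_onset_class, drug_tokens,
    ifelse(nzchar(drug_tokens), paste(onset_class, drug_tokens, sep = ";"),
           onset_class))

  # chronic conditions, member-level and persistent
  cc_base <- 0.32 * 0.90^(seq_len(33L) - 1L)
  cc_shift <- pull("conditions", "logit_shift") +
    pull("conditions", "severity_slope") * s
  Qcc <- matrix(qlogis(cc_base), n, 33L, byrow = TRUE)
  condM <- matrix(runif(n * 33L), n) < plogis(Qcc + cc_shift)
  cond_tokens <- tokens_from_matrix(condM, CHRONIC_CONDITION_NAMES)

  # frailty propensity, correlated with severity
  fcorr <- pull("frailty", "severity_corr")
  g <- fcorr * s + sqrt(1 - fcorr^2) * rnorm(n)
  f_base <- pullm("frailty", "base")[ai, , drop = FALSE]
  f_lam <- pull("frailty", "member_sd")

  # pharmacy share: member-level mean, Beta-distributed annual draws
  ph_mean <- plogis(pull("pharmacy", "mean_logit") +
                      pull("pharmacy", "severity_slope") * s +
                      pull("pharmacy", "member_sd") * rnorm(n))
  ph_kap <- pull("pharmacy", "concentration")

  # medical split of non-pharmacy cost (inpatient, outpatient, physician);
  # frailer members tilt toward inpatient care
  Wsplit <- pullm("cost", "medical_split")[ai, , drop = FALSE]
  Wsplit <- Wsplit / rowSums(Wsplit)
  conc <- pull("cost", "split_concentration")
  ip_tilt <- pull("cost", "inpatient_frailty_tilt")

  # frailer members are more event-prone (falls, fractures, acute admissions)
  p_event <- plogis(qlogis(pmax(1e-12, pull("event", "prob"))) +
                      pull("event", "frailty_tilt") * g)
  p_event[pull("event", "prob") <= 0] <- 0
  ev_mu <- pull("event", "meanlog")
  ev_sd <- pull("event", "sdlog")
  ev_carry <- pull("event", "aftermath")
  d0 <- pull("death", "intercept")
  d1 <- pull("death", "severity_slope")
  de1 <- pull("death", "event_boost")
  de0 <- pull("death", "post_event_boost")
  de_decay <- pull("death", "post_event_decay")
  eol <- pull("death", "eol_cost_mult")
  day_cost <- pull("utilization", "hospital_day_cost")
  prov_mu <- pull("utilization", "providers_mean")
  spec_mu <- pull("utilization", "specialties_mean")
  proc_shift <- pull("procedures", "logit_shift")
  proc_slope <- pull("procedures", "severity_slope")
  proc_base <- c(0.30, 0.35, 0.45,
                 0.45 * 0.88^(seq_len(length(PROCEDURE_CATEGORY_NAMES) - 3L)))

  gap <- runif(n) < config$gap_probability
  gap_year <- years[sample.int(ny, n, replace = TRUE)]
  gap_month <- sample.int(12L, n, replace = TRUE)
  mstr <- month_prefix_strings()
  gap_strings <- vapply(1:12, function(m) {
    paste(setdiff(1:12, m), collapse = ";")
  }, character(1))

  ## ---- year loop ----------------------------------------------------------
  alive <- rep(TRUE, n)
  # event history drives decaying post-acute excess mortality: the hazard
  # boost is de0 the year after an event, then fades geometrically
  ev_hist <- numeric(n)
  ev_cost_prev <- numeric(n)
  u <- rnorm(n)
  rows <- vector("list", ny)

  for (t in seq_len(ny)) {
    if (t > 1L) u <- rho * u + sqrt(1 - rho^2) * rnorm(n)
    ev <- runif(n) < p_event
    z <- (tau * s + sig * u) / zden
    hazard <- plogis(d0 + d1 * z + de1 * ev + de0 * ev_hist)
    dies <- alive & (runif(n) < hazard)
    dmonth <- sample.int(12L, n, replace = TRUE)

    base_cost <- exp(mu + tau * s + sig * u)
    # acute event spike (inpatient) plus post-acute aftermath care in the
    # year after an event (rehabilitation and follow-up -> outpatient)
    ev_spike <- ifelse(ev, rlnorm(n, ev_mu, ev_sd), 0)
    ev_after <- ev_carry * ev_cost_prev
    ev_cost <- ev_spike + ev_after
    share <- rbeta(n, ph_mean * ph_kap, (1 - ph_mean) * ph_kap)
    pharm <- share * base_cost
    med <- base_cost - pharm
    w1 <- rgamma(n, conc * Wsplit[, 1L]) * exp(ip_tilt * g)
    w2 <- rgamma(n, conc * Wsplit[, 2L])
    w3 <- rgamma(n, conc * Wsplit[, 3L])
    ws <- w1 + w2 + w3
    inpat <- med * w1 / ws + ev_spike
    outpat <- med * w2 / ws + ev_after
    phys <- med * w3 / ws

    # death-year claims are partial (through the death month), with an
    # end-of-life intensity multiplier
    f <- ifelse(dies, pmin(1, (dmonth - 0.5) / 12) * eol, 1)
    pharm <- round(pharm * f, 2)
    inpat <- round(inpat * f, 2)
    outpat <- round(outpat * f, 2)
    phys <- round(phys * f, 2)

    frailM <- matrix(runif(n * 7L), n, 7L) <
      plogis(qlogis(f_base) + f_lam * g)
    frail_tokens <- tokens_from_matrix(frailM, frailty_component_names())

    procM <- matrix(runif(n * length(proc_base)), n) <
      plogis(matrix(qlogis(proc_base), n, length(proc_base), byrow = TRUE) +
               proc_shift + proc_slope * z)
    proc_tokens <- tokens_from_matrix(procM, PROCEDURE_CATEGORY_NAMES)

    hosp_days <- rpois(n, pmin(45, inpat / day_cost))
    providers <- 1L + rpois(n, prov_mu * exp(0.18 * z))
    specialties <- 1L + rpois(n, spec_mu * exp(0.15 * z))

    enr <- rep(mstr[12L], n)
    is_gap <- gap & gap_year == years[t] & !dies
    enr[is_gap] <- gap_strings[gap_month[is_gap]]
    enr[dies] <- mstr[dmonth[dies]]

    keep <- which(alive)
    rows[[t]] <- data.table(
      member_id = member_id[keep],
      year = years[t],
      total_cost = (pharm + inpat + outpat + phys)[keep],
      pharmacy_cost = pharm[keep],
      inpatient_cost = inpat[keep],
      outpatient_cost = outpat[keep],
      physician_cost = phys[keep],
      hospital_days = hosp_days[keep],
      enrolled_months = enr[keep],
      death_month = ifelse(dies[keep], dmonth[keep], NA_integer_),
      age = age0[keep] + (years[t] - years[1L]),
      sex = sex[keep],
      race = race[keep],
      dual_eligible = dual[keep],
      ses_index = ses[keep],
      geography = geography[keep],
      chronic_conditions = cond_tokens[keep],
      frailty_components = frail_tokens[keep],
      drug_categories = ifelse(t >= onset_year_idx[keep],
                               drug_tokens_onset[keep], drug_tokens[keep]),
      procedure_categories = proc_tokens[keep],
      esrd_or_dialysis = esrd[keep],
      distinct_providers = providers[keep],
      distinct_specialties = specialties[keep]
    )

    alive <- alive & !dies
    ev_hist <- pmax(de_decay * ev_hist, as.numeric(ev))
    ev_cost_prev <- ev_cost
  }

  panel <- rbindlist(rows)
  setorder(panel, member_id, year)
  setcolorder(panel, PANEL_COLUMNS)
  panel[]
}
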