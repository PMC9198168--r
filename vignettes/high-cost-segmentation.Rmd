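---
title: "Segmenting the top spending decile of a longitudinal claims panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the top spending decile of a longitudinal claims panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spendseg)
library(data.table)
```

## The problem

In Medicare Advantage populations, the most expensive tenth of enrollees
accounts for the majority of total healthcare spending, yet interventions
that target members on cost alone have repeatedly under-delivered. One
reason is temporal heterogeneity: a member can be in the top cost decile
this year because of a one-off acute event, because of ongoing expensive
therapy, or because of accumulating chronic complexity — and these three
situations have very different prognoses, mortality, and levers for
intervention.

`spendseg` implements a longitudinal segmentation of the top decile into
three groups, classified per member-year `t` in strict order of precedence:

1. **Catastrophic** — total cost below the 60th percentile in year `t − 1`
   and at or above the 90th percentile in year `t`: an acute cost shock.
2. **Persistent** — top-decile members, not catastrophic, with at least one
   marker of structurally high spend: dialysis or end-stage renal disease;
   use of a chronic drug class (antineoplastics, DMARDs, phosphate-removing
   agents, immunomodulatory agents, HIV NRTIs); pharmacy cost at or above
   60% of total cost; or age under 65 at the baseline year (disability- or
   ESRD-based eligibility).
3. **Semi-persistent** — the remainder of the top decile: chronically
   complex members with fluctuating spend.

Around the classifier the package provides the full analysis pipeline:
cohort construction under continuous-enrollment rules, per-year
equal-frequency cost deciles, year-over-year flow tables with a death
state, one-year mortality by group, pharmacy-spend persistence, frailty
prevalence, group characteristics tables with chi-square/ANOVA comparisons,
and two multinomial-logit odds-ratio analyses with L1-penalized variable
selection.

Real claims data of this kind are proprietary, so the package also ships a
calibrated synthetic claims generator. Everything downstream of
`generate_population()` treats the panel as it would treat real data.

## The synthetic generator

### Model

Members are drawn from a mixture of five latent archetypes — `HEALTHY`,
`FLUCTUATING_CHRONIC`, `MED_DEPENDENT`, `EVENT_PRONE`, `FRAIL_COMPLEX`.
For member $i$ of archetype $a$ in year $t$, annual total cost is

$$\log C_{it} = \mu_a + \tau_a s_i + \sigma_a u_{it}, \qquad
  u_{it} = \rho_a u_{i,t-1} + \sqrt{1-\rho_a^2}\,\varepsilon_{it},$$

with $s_i \sim N(0,1)$ a member-level severity intercept and $u_{it}$ a
standard-normal AR(1) year process. The lognormal family produces the
heavy right tail seen in claims data (mean well above median every year)
and the member intercept plus AR(1) produce year-to-year cost-decile
persistence.

Three further mechanisms turned out to be necessary for the joint flow
statistics and are worth stating explicitly:

* **Catastrophic events with aftermath.** With archetype-specific annual
  probability, a lognormal inpatient cost spike is added; the following
  year a fraction (`event$aftermath`) of the spike recurs as post-acute
  care. Without the aftermath term essentially no cost-shock member stays
  in the top decile a second year, whereas roughly a fifth should.
* **Chronic-drug onset.** The five persistent-defining drug-class flags are
  member-level (chronic therapy), but members may also newly start one such
  therapy in a later year (`drugs$annual_incidence`), the flag persisting
  thereafter. This is what lets a few percent of semi-persistent members
  become persistent the next year; with purely static flags that flow is
  structurally near zero.
* **Post-acute excess mortality.** Death fires annually from a logistic
  hazard in the member's current severity z-score, boosted during an event
  year and — with geometric decay — in the years after one. Death months
  are uniform within the year (the source analyses state no within-year
  timing); death-year claims are the observed partial year scaled by an
  end-of-life intensity multiplier, with no annualization.

Pharmacy share of annual cost is Beta-distributed around a member-level
mean tied to severity; the non-pharmacy remainder is split across
inpatient/outpatient/physician by archetype-specific Dirichlet draws.
Chronic-condition flags (33 category slots) are member-constant;
frailty-component flags (7 domains) are drawn per year around a
member-level propensity correlated with severity; procedure categories and
utilization counts scale with the year's severity.

The archetypes are a modelling device only. The generator never emits the
latent label, and the segmentation must recover the group structure from
costs and category-level flags alone — this keeps every downstream test
honest.

### Calibration

`default_config()` is the packaged calibration. It was tuned once, offline,
by heuristic search so that the full pipeline applied to a generated panel
(150,000 members, 2016–2019) reproduces the twelve headline statistics in
`calibration_targets()`: 45% overall top-decile retention; group shares of
24.6 / 42.7 / 32.0% (catastrophic / semi-persistent / persistent); 80.6%
catastrophic exit with 13.9% one-year mortality; 57.7% persistent
retention; 27.8% semi-persistent retention and 68.4% exit; 79% top-decile
retention among pharmacy-dominated spenders, who are 18.5% of the decile;
and 71% any-frailty prevalence among semi-persistent members.
`calibration_report()` recomputes all of them from scratch on any panel.
The defaults are study conditions, not tuning knobs: they are not meant to
be adjusted at run time, and the acceptance machinery regenerates the panel
fresh on every run.

The simulated dollar scale is arbitrary (segmentation uses within-year
ranks and cost ratios only), and the generator makes no attempt to match
real-data dollar thresholds, which the source analyses do not publish.

### What the generator does not emulate

No claim lines, diagnosis/procedure/drug *codes* (only category-level
flags; real-code mapping is a pluggable upstream step), no plan switching,
benefit design, cost inflation, provider networks, or geographic detail
beyond a categorical flag. Passing calibration therefore shows that the
*pipeline* computes the intended quantities on data with realistic joint
structure — not that the generator is a substitute for real claims in
substantive research.

## Running the pipeline

```{r pipeline, eval = FALSE}
panel <- generate_population(default_config(), seed = 1,
                             n_members = 150000)

# two cohorts: the primary (death-exclusive) and the mortality-inclusive one
ex  <- filter_continuous_enrollment(panel, cohort_spec(2016, 2019, FALSE))
inc <- filter_continuous_enrollment(panel, cohort_spec(2016, 2019, TRUE))

seg <- segment_panel(inc)             # deciles, thresholds, groups 2017-2019
g17 <- seg$groups[year == 2017]

origins <- g17[group != "BOTTOM90" &
                 !member_id %in% deaths_in_year(inc, 2017)]
fl <- group_flows(origins, seg$groups[year == 2018], seg$assignments,
                  deaths_in_year(inc, 2018))
round(100 * fl$row_proportions, 1)

calibration_report(panel)
```

## Design decisions

**Rank-based deciles.** Ten *equally sized* groups cannot be guaranteed by
threshold comparison when costs tie (zero-cost member-years are common), so
decile membership is assigned by sorting on `(total_cost, member_id)` and
slicing ranks: member at rank $r$ of $n$ gets decile $\lceil 10r/n\rceil$.
Decile sizes differ by at most one for any input, the assignment is
deterministic and independent of row order, and the thresholds
(cost at rank $\lceil kn/10\rceil$) are still reported for interpretation
and for the catastrophic rule's P60 comparison. Member id is an opaque,
attribute-free key, so breaking ties by id introduces no bias. Thresholds
are recomputed per cohort — including decedents' partial-year claims
raises the top-decile bar noticeably, so the two cohorts must not share
thresholds.

**Rule details.** The catastrophic comparison uses strict `<` on the
recorded year `t − 1` P60 value. The pharmacy criterion uses `>= 0.60`
both in the persistent rule and in the descriptive "pharmacy-dominated"
statistics (the source wording mixes "at or above 60%" and "> 60%"; one
threshold is used throughout and the boundary case fires the criterion).
The under-65 test is evaluated once, against age at the first panel year.
A member's pharmacy ratio with zero total cost is defined as 0. A
structural consequence of the precedence is that top-decile members under
65 at baseline can only be catastrophic or persistent — never
semi-persistent — which the suite asserts as an invariant.

**Flows and mortality.** One-year mortality of a year-`t` group is death
during calendar year `t + 1`; members dying during year `t + 1` route to
`DIED` regardless of their partial-year spend, so the `DIED` column of a
flow table equals the mortality rates exactly by construction. Members who
die during year `t` itself are part of the year-`t` group composition but
have no year-`t + 1` state and are excluded from flow origins. Survivors
leaving the top decile land in bands derived from the same decile
assignment: deciles 1–6 (`P0_60`) and 7–9 (`P60_90`). A top-decile origin
can never have destination `CATASTROPHIC` (its year-`t` cost is above the
year-`t` P60), and the flow table keeps that column as an asserted
structural zero.

**Frailty cost contrast.** The published comparison ("semi-persistent
members with frailty in both the index and prior year had higher inpatient
costs at the index year and the next") is ambiguous about conditioning;
`frailty_cost_contrast()` implements: index-year semi-persistent
membership, at least one frailty component in both the index and the prior
year, ratios of *means* (not medians) at horizons 0 and +1.

**Statistical tests.** Categorical comparisons use chi-square tests of
independence without continuity correction (multi-level tables dominate;
the 2×2 worked example in the suite is checked against the closed form);
continuous ones use one-way ANOVA. Pairwise follow-ups (chi-square,
Welch t) are reported with unadjusted p-values, as is conventional for
descriptive cohort tables of this kind. Standard errors accompany means
only (SD/√n); percentages are reported bare.

**Odds-ratio models.** Both analyses use a two-step procedure:
L1-penalized multinomial logit over standardized-continuous/raw-binary
predictors, with the penalty chosen by 5-fold cross-validated deviance on a
geometric grid of 20 values (seeded fold assignment); then an unpenalized
refit on the selected predictors at original scale, reporting
exp(coefficients) with Wald standard errors and unadjusted p-values
against the reference class (`BOTTOM90`, or 0 top-decile years). The
penalty's role is collinearity pruning, not shrinkage of the reported
estimates — hence the refit. Exact duplicate predictor columns are dropped
before selection; coefficients exceeding 15 on the per-SD scale trigger a
separation error naming the feature. The predictor universe defaults to
all 33 condition flags, 7 frailty components, the 5 chronic drug classes,
3 named procedure categories, utilization counts and demographics;
selection is fit per predictor year rather than pooled across years.

**Numerical conventions.** Costs are stored in cents-rounded dollars and
category costs must sum to the total within $0.01. Enrollment is monthly;
a "gap" is any window month with no enrollment, and partial months count
as enrolled. Set-valued fields travel as `;`-delimited token strings in
both the in-memory tables and the CSV contract, with an empty string for
the empty set.

## Problem sizes and reproducibility

The calibration targets are verified on a 150,000-member, four-year panel
(about 580,000 member-year rows), the size at which the quoted tolerances
(±1.5–2 percentage points) comfortably exceed binomial sampling error for
a ~15,000-member decile. Unit and property tests use panels of a few
hundred to 20,000 members, and brute-force oracle comparisons use 40–50
member panels where exhaustive reimplementation is feasible. All
randomness flows through explicit integer seeds: `generate_population()`
is bit-reproducible given `(config, seed)`, and the odds-ratio fold
assignment is seeded separately.

## Known limitations

* Death-year costs are partial-year observations deliberately left
  unannualized; deciles over the death-inclusive cohort are therefore
  biased against decedents' true annual run rate.
* The generator's demographic margins (race, geography, SES) are plausible
  but not calibrated; only the flow/mortality/pharmacy/frailty statistics
  listed in `calibration_targets()` are. Secondary flow cells outside that
  list diverge from their real-data analogues — notably, survivors leaving
  the top decile land mostly in the 60th–90th percentile band rather than
  splitting evenly with the lower band, and the persistent and
  semi-persistent one-year mortality rates run a few points below the
  published ones (only the catastrophic rate is a calibration target).
* Real odds-ratio magnitudes for specific conditions are figure-only in
  the source material and proprietary-data-dependent; the association
  module is validated by parameter recovery on known truths and sign
  checks on generator-implied associations instead.
* Whether the source analyses pooled 2016–2018 predictor years in one
  selection fit is unstated; fitting per year is a documented choice.
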