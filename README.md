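# spendseg

Segmentation and temporal flow analysis of the top spending decile in
longitudinal healthcare claims panels.

## The problem

In Medicare Advantage populations the most expensive 10% of enrollees
account for the majority of spending, but "high cost" is not one
phenotype. `spendseg` classifies each top-decile member-year `t` into three
groups, in strict order of precedence:

1. **Catastrophic** — annual cost below the 60th percentile in year `t − 1`
   and at or above the 90th percentile in year `t` (an acute cost shock);
2. **Persistent** — top-decile, not catastrophic, and at least one of:
   dialysis/ESRD; use of a chronic drug class (antineoplastics, DMARDs,
   phosphate-removing agents, immunomodulatory agents, HIV NRTIs);
   pharmacy cost ≥ 60% of total cost; age < 65 at baseline;
3. **Semi-persistent** — the rest of the top decile (chronic complexity
   with fluctuating spend).

Around the classifier the package implements the full longitudinal
pipeline: continuous-enrollment cohort construction (with and without
decedents), per-year equal-frequency cost deciles with deterministic tie
handling, year-over-year group flow tables with a death state, one-year
mortality by group, pharmacy-spend persistence, claims-based frailty
summaries (7 components), group characteristics tables with
chi-square/ANOVA comparisons, and two multinomial-logit odds-ratio
analyses (L1-penalized selection, unpenalized refit).

Because claims data of this kind are proprietary, the package ships a
calibrated synthetic claims generator: a mixture of five latent member
archetypes with lognormal AR(1) annual costs, catastrophic-event spikes
with post-acute aftermath, archetype- and severity-dependent death
hazards, and category-level clinical flags (33 chronic conditions, 7
frailty components, AHFS-style drug classes, CCS-style procedure
classes). Its default calibration reproduces the headline flow statistics
reported for a large real Medicare Advantage cohort; see
`calibration_targets()` and the vignette.

## Worked example

```r
library(spendseg)

panel <- generate_population(default_config(), seed = 1,
                             n_members = 150000)

# death-inclusive cohort, classify 2017, flows into 2018
inc <- filter_continuous_enrollment(panel, cohort_spec(2016, 2019, TRUE))
seg <- segment_panel(inc)
g17 <- seg$groups[year == 2017]
table(g17$group)
#>        BOTTOM90    CATASTROPHIC      PERSISTENT SEMI_PERSISTENT
#>          126349            3447            4515            6077

origins <- g17[group != "BOTTOM90" &
                 !member_id %in% deaths_in_year(inc, 2017)]
fl <- group_flows(origins, seg$groups[year == 2018], seg$assignments,
                  deaths_in_year(inc, 2018))
round(100 * fl$row_proportions, 1)
#>                  destination
#> origin            P0_60 P60_90 CATASTROPHIC PERSISTENT SEMI_PERSISTENT DIED
#>   CATASTROPHIC      4.4   61.3            0        4.0            16.3 13.9
#>   PERSISTENT        2.0   29.1            0       57.9             1.2  9.9
#>   SEMI_PERSISTENT   5.4   48.4            0        3.3            29.1 13.7
```

Read each row as "of the members in this group in 2017, where were they in
2018": for example, most catastrophic members leave the top decile the
next year, while the persistent group largely stays put — the temporal
signature that motivates treating the three groups differently. (The
numbers above are from the synthetic default calibration at `seed = 1`;
regenerate them with the snippet. The exact rates the packaged calibration
is required to reproduce, with tolerances, are in
`calibration_targets()`, and `calibration_report(panel)` checks any panel
against them.)

The generator and pipeline are also available from a shell:

```sh
Rscript inst/cli/spendseg.R simulate --seed 1 --n 50000 --out panel.csv
Rscript inst/cli/spendseg.R segment  --panel panel.csv --year 2017 --out groups.csv
Rscript inst/cli/spendseg.R flows    --panel panel.csv --from-year 2017 --to-year 2018 --out flows.csv
```

## Package layout

* `R/config.R`, `R/simulate.R` — generator configuration and simulation
* `R/cohort.R` — member-year contract, CSV I/O, enrollment filters
* `R/deciles.R` — thresholds, rank-based decile assignment, transitions
* `R/segmentation.R` — the three-group classifier
* `R/transitions.R` — group flows, mortality, pharmacy persistence, frailty contrast
* `R/reporting.R` — characteristics tables, tests, frailty prevalence
* `R/association.R` — feature builders and the L1-plus-refit odds-ratio fit
* `R/calibration.R` — headline statistics and the calibration report
* `vignettes/high-cost-segmentation.Rmd` — models, assumptions, design decisions
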