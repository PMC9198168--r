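# Field-level vocabularies shared across modules. These are category-level
# labels, not billing codes: real ICD/NDC/CPT-to-category mapping is a
# pluggable upstream step the package does not ship.

#' Names of the seven claims-based frailty components
#'
#' Indicator domains derived from claims: falls and fractures, anxiety and
#' depression, mobility problems, dementia and delirium, pressure ulcers and
#' weight loss, dependence and care, and incontinence.
#'
#' @return Character vector of length 7.
#' @export
frailty_component_names <- function() {
  c("falls_fractures", "anxiety_depression", "mobility", "dementia_delirium",
    "ulcers_weight_loss", "dependence_care", "incontinence")
}

#' Drug categories that define the persistent group
#'
#' The five chronic pharmacologic-therapeutic classes whose use marks ongoing,
#' expensive disease management: antineoplastic agents, disease-modifying
#' antirheumatic agents (DMARDs), phosphate-removing agents, immunomodulatory
#' agents, and HIV nucleoside/nucleotide reverse transcriptase inhibitors.
#'
#' @return Character vector of length 5.
#' @export
persistent_drug_classes <- function() {
  c("antineoplastic", "dmard", "phosphate_removing", "immunomodulatory",
    "hiv_nrti")
}

# Spend-group labels, in reporting order.
GROUP_LEVELS <- c("BOTTOM90", "CATASTROPHIC", "PERSISTENT", "SEMI_PERSISTENT")
TOP_GROUPS <- c("CATASTROPHIC", "PERSISTENT", "SEMI_PERSISTENT")

# Destination states of a group flow table. CATASTROPHIC is a structural
# zero from any top-decile origin (a year-t top-decile member cannot be below
# the year-t 60th percentile) but is kept as an explicit column.
FLOW_DESTINATIONS <- c("P0_60", "P60_90", "CATASTROPHIC", "PERSISTENT",
                       "SEMI_PERSISTENT", "DIED")

PERSISTENT_CRITERIA <- c("ESRD_DIALYSIS", "CHRONIC_DRUG", "PHARMACY_RATIO",
                         "UNDER_65_2016")

RACE_LEVELS <- c("Asian", "Black", "Hispanic", "Native American", "Other",
                 "White", "Missing")
GEO_LEVELS <- c("rural", "suburban", "urban", "missing")

CHRONIC_CONDITION_NAMES <- sprintf("cc%02d", 1:33)

# Procedure-category universe used by the generator: a handful of named
# classes that matter downstream plus generic filler categories.
PROCEDURE_CATEGORY_NAMES <- c(
  "dme_supplies", "chest_xray", "nonhospital_care",
  sprintf("ccs%02d", 4:30)
)

# Background (non-persistent-defining) 2-digit drug class codes.
BACKGROUND_DRUG_CLASSES <- sprintf("ahfs%02d",
  c(4, 8, 10, 12, 20, 24, 28, 36, 40, 48, 52, 56, 68, 72, 84, 86, 92))

# Required columns of a member-year claims panel, in canonical order.
PANEL_COLUMNS <- c(
  "member_id", "year", "total_cost", "pharmacy_cost", "inpatient_cost",
  "outpatient_cost", "physician_cost", "hospital_days", "enrolled_months",
  "death_month", "age", "sex", "race", "dual_eligible", "ses_index",
  "geography", "chronic_conditions", "frailty_components", "drug_categories",
  "procedure_categories", "esrd_or_dialysis", "distinct_providers",
  "distinct_specialties"
)
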