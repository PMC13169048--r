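#' Item registries
#'
#' Canonical identifiers for every instrument item the package codes. These
#' are the single source of truth for column names in the wide participant
#' table and for the rule engine's symptom universe.
#'
#' @name item_registry
#' @keywords internal
NULL

# ICD-10 F32 core symptoms (exactly three).
cisr_core_items <- c("depressed_mood", "loss_of_interest", "fatigue")

# Additional symptoms administered under the study protocol.
cisr_additional_items <- c(
  "concentration", "self_esteem_low", "guilt",
  "pessimism_or_suicidality", "sleep_disturbance", "agitation_or_retardation"
)

# Items representable in a profile but unset under the default administration;
# these are the ones a sensitivity run imputes as present.
cisr_excludable_items <- c("appetite_change", "weight_change", "impairment")

cisr_all_items <- c(cisr_core_items, cisr_additional_items, cisr_excludable_items)

# Somatic-syndrome criteria retained after dropping appetite/weight.
somatic_flag_ids <- c(
  "diurnal_variation", "early_waking", "loss_of_reactivity",
  "libido_loss", "psychomotor_change"
)

# 12-item threatening life events inventory (previous 12 months).
life_event_ids <- c(
  "illness_self", "illness_relative", "death_parent_child_spouse",
  "death_friend_relative", "marital_separation", "relationship_breakup",
  "problems_close_person", "unemployed_seeking", "lost_job",
  "financial_crisis", "police_court", "loss_theft_valued"
)

# 5-item discrimination battery (previous 12 months).
discrimination_ids <- c(
  "unfair_treatment_work", "job_refusal", "physical_attack",
  "property_damage", "racial_insults"
)

comorbidity_ids <- c(
  "hypertension", "diabetes_t1", "diabetes_t2", "obesity",
  "cardiovascular", "cancer", "copd", "autoimmune"
)

ethnicity_levels <- c("white_british", "south_asian", "black", "other")
education_levels <- c(
  "none", "school_incomplete", "school_complete",
  "university_or_apprenticeship", "other"
)
occupation_levels <- c(
  "unemployed", "employed", "retired", "student",
  "housewife", "off_sick", "other"
)
marital_levels <- c("single", "married", "divorced_separated", "widowed")
smoking_levels <- c("never", "past", "current")
sex_levels <- c("male", "female")

# HAMD-17 per-item maxima: nine items scored 0-4, eight scored 0-2 (max 52).
hamd_item_max <- c(4, 4, 4, 2, 2, 2, 4, 4, 4, 4, 4, 2, 2, 2, 4, 2, 2)

#' Column names of the wide participant table
#'
#' @return Character vector of all columns `validate_input()` requires.
#' @export
participant_columns <- function() {
  c(
    "participant_id", "age", "sex", "ethnicity", "education", "occupation",
    "marital_status", "smoking", "alcohol",
    paste0("le_", life_event_ids),
    paste0("disc_", discrimination_ids),
    paste0("cm_", comorbidity_ids),
    paste0("cisr_", c(cisr_core_items, cisr_additional_items)),
    "cisr_duration_weeks",
    paste0("som_", somatic_flag_ids),
    paste0("phq2_", 1:2),
    paste0("hamd_", 1:17)
  )
}
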