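# Independent oracles and fixture builders.

# Direct transcription of the ICD-10 F32 operationalisation for the nine
# administered items: written as plain branches, independent of the
# rule-table engine it checks.
oracle_classify <- function(bits9, duration, som_count) {
  core <- sum(bits9[1:3])
  total <- sum(bits9)
  if (duration < 2 || core < 2 || total < 4) {
    cat_ <- "none"
  } else if (total <= 5) {
    cat_ <- "mild"
  } else {
    cat_ <- "moderate_severe"
  }
  severe <- cat_ == "moderate_severe" && total >= 8 && core == 3
  somatic <- cat_ != "none" && som_count >= 3
  list(category = cat_, severe = severe, somatic = somatic, total = total)
}

# Profile from a 9-bit endorsement vector (core items first).
profile_from_bits <- function(bits9, duration = 4, som_count = 0) {
  items <- c("depressed_mood", "loss_of_interest", "fatigue",
             "concentration", "self_esteem_low", "guilt",
             "pessimism_or_suicidality", "sleep_disturbance",
             "agitation_or_retardation")
  args <- as.list(as.logical(bits9))
  names(args) <- items
  args$duration_weeks <- duration
  args$somatic_flags <- c("diurnal_variation", "early_waking",
                          "loss_of_reactivity", "libido_loss",
                          "psychomotor_change")[seq_len(som_count)]
  do.call(symptom_profile, args)
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration over all tables with the observed margins (the classic
# sum-of-probabilities-not-exceeding-observed definition).
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]) # row-1 margin
  n2 <- sum(tab[2, ])
  k <- sum(tab[, 1]) # col-1 margin
  a_obs <- tab[1, 1]
  a_range <- max(0, k - n2):min(m, k)
  probs <- stats::dhyper(a_range, m, n2, k)
  p_obs <- stats::dhyper(a_obs, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Minimal wide participant table with all required columns, defaults benign.
blank_records <- function(n) {
  cols <- participant_columns()
  rec <- as.data.frame(stats::setNames(
    lapply(cols, function(cn) rep(0L, n)), cols))
  rec$participant_id <- sprintf("X%03d", seq_len(n))
  rec$age <- rep(60L, n)
  rec$sex <- rep("male", n)
  rec$ethnicity <- rep("white_british", n)
  rec$education <- rep("school_complete", n)
  rec$occupation <- rep("retired", n)
  rec$marital_status <- rep("married", n)
  rec$smoking <- rep("never", n)
  rec
}
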