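test_that("empty profile classifies as no depression", {
  dx <- classify(symptom_profile(), rules_default())
  expect_equal(as.character(dx$category), "none")
  expect_equal(dx$total_count, 0L)
  expect_false(dx$somatic_syndrome)
})

test_that("four symptoms with two core over four weeks grade mild; imputation upgrades the episode", {
  p <- symptom_profile(depressed_mood = TRUE, loss_of_interest = TRUE,
                       concentration = TRUE, sleep_disturbance = TRUE,
                       duration_weeks = 4)
  dx <- classify(p, rules_default())
  expect_equal(as.character(dx$category), "mild")
  expect_equal(dx$total_count, 4L)

  # sensitivity rules impute appetite, weight and impairment as endorsed
  dx_s <- classify(p, rules_sensitivity())
  expect_equal(as.character(dx_s$category), "moderate_severe")
  expect_equal(dx_s$total_count, 7L)
})

test_that("rule engine agrees with the brute-force ICD-10 transcription on the exhaustive grid", {
  rules <- rules_default()
  grid_bits <- as.matrix(expand.grid(rep(list(0:1), 9)))
  got_cat <- want_cat <- character(0)
  got_sev <- want_sev <- got_som <- want_som <- logical(0)
  got_tot <- want_tot <- integer(0)
  for (duration in c(0, 1, 2, 4)) {
    for (som in 0:5) {
      for (i in seq_len(nrow(grid_bits))) {
        bits <- grid_bits[i, ]
        got <- classify(profile_from_bits(bits, duration, som), rules)
        want <- oracle_classify(bits, duration, som)
        got_cat <- c(got_cat, as.character(got$category))
        want_cat <- c(want_cat, want$category)
        got_sev <- c(got_sev, got$severe_subflag)
        want_sev <- c(want_sev, want$severe)
        got_som <- c(got_som, got$somatic_syndrome)
        want_som <- c(want_som, want$somatic)
        got_tot <- c(got_tot, got$total_count)
        want_tot <- c(want_tot, want$total)
      }
    }
  }
  expect_equal(length(got_cat), 2^9 * 4 * 6)
  expect_identical(got_cat, want_cat)
  expect_identical(got_sev, want_sev)
  expect_identical(got_som, want_som)
  expect_identical(got_tot, want_tot)
})

test_that("adding an endorsed symptom never lowers the category", {
  set.seed(11)
  rules <- rules_default()
  lv <- c(none = 0, mild = 1, moderate_severe = 2)
  for (rep in 1:200) {
    bits <- rbinom(9, 1, 0.4)
    dur <- sample(c(0, 2, 4), 1)
    base <- lv[[as.character(classify(profile_from_bits(bits, dur), rules)$category)]]
    off <- which(bits == 0)
    if (length(off) == 0) next
    bits2 <- bits
    bits2[sample(off, 1)] <- 1L
    up <- lv[[as.character(classify(profile_from_bits(bits2, dur), rules)$category)]]
    expect_gte(up, base)
  }
})

test_that("excluded item values never influence an as-administered classification", {
  set.seed(12)
  rules <- rules_default()
  for (rep in 1:50) {
    bits <- rbinom(9, 1, 0.5)
    dur <- sample(c(1, 2, 4), 1)
    base_args <- as.list(as.logical(bits))
    names(base_args) <- c("depressed_mood", "loss_of_interest", "fatigue",
                          "concentration", "self_esteem_low", "guilt",
                          "pessimism_or_suicidality", "sleep_disturbance",
                          "agitation_or_retardation")
    base_args$duration_weeks <- dur
    unset <- classify(do.call(symptom_profile, base_args), rules)
    set_args <- c(base_args, list(appetite_change = TRUE, weight_change = TRUE,
                                  impairment = TRUE))
    set_ <- classify(do.call(symptom_profile, set_args), rules)
    expect_identical(unset, set_)
  }
})

test_that("apply_sensitivity endorses excluded items and is idempotent", {
  p <- symptom_profile(depressed_mood = TRUE, duration_weeks = 4)
  expect_true(is.na(p$appetite_change))
  q <- apply_sensitivity(p)
  expect_true(q$appetite_change)
  expect_true(q$weight_change)
  expect_true(q$impairment)
  expect_identical(apply_sensitivity(q), q)
  # other fields unchanged
  expect_identical(q$depressed_mood, p$depressed_mood)
  expect_identical(q$duration_weeks, p$duration_weeks)
  # requires sensitivity rules
  expect_error(apply_sensitivity(p, rules_default()), "impute_present")
})

test_that("sensitivity imputation never lowers, and typically raises, cohort prevalence", {
  set.seed(13)
  lv <- c(none = 0, mild = 1, moderate_severe = 2)
  for (rep in 1:20) {
    profiles <- lapply(1:40, function(i) {
      profile_from_bits(rbinom(9, 1, runif(1, 0.2, 0.7)),
                        duration = sample(c(0, 2, 4, 8), 1),
                        som_count = sample(0:5, 1))
    })
    base <- classify_cohort(profiles, rules_default())
    sens <- classify_cohort(profiles, rules_sensitivity())
    expect_true(all(lv[as.character(sens$category)] >=
                      lv[as.character(base$category)]))
    expect_gte(sum(sens$category == "moderate_severe"),
               sum(base$category == "moderate_severe"))
  }
})

test_that("cohort classification preserves order and attaches the participant index to errors", {
  empties <- lapply(1:3, function(i) symptom_profile())
  dx <- classify_cohort(empties)
  expect_equal(nrow(dx), 3)
  expect_true(all(dx$category == "none"))

  mixed <- list(
    profile_from_bits(c(1, 1, 0, 1, 1, 0, 0, 0, 0), 4),  # total 4 -> mild
    profile_from_bits(rep(1, 9), 8, som_count = 4),       # total 9 -> severe
    symptom_profile()
  )
  dx <- classify_cohort(mixed)
  expect_equal(as.character(dx$category),
               c("mild", "moderate_severe", "none"))
  expect_true(dx$severe_subflag[2])
  expect_true(dx$somatic_syndrome[2])
})

test_that("vectorized table classification matches the scalar engine on both rule tables", {
  coh <- generate_cohort(preset_dialysis(n = 400, seed = 31))
  profiles <- dialdep:::profiles_from_records(coh$records)
  for (rules in list(rules_default(), rules_sensitivity())) {
    expect_identical(classify_cohort(coh$records, rules),
                     classify_cohort(profiles, rules))
  }
})

test_that("rule-table validation rejects bad configurations and bad inputs", {
  expect_error(rule_table(excluded_items = c("appetite_change", "nonsense")),
               "unknown item")
  expect_error(rule_table(mild_total_range = c(4, 7)), "disjoint")
  expect_error(rule_table(min_core_for_episode = 1), "2 or 3")
  expect_error(symptom_profile(duration_weeks = -1), "non-negative")
  expect_error(symptom_profile(somatic_flags = "weird_flag"), "somatic flag")
})

test_that("rule tables round-trip through YAML and shipped presets load", {
  tmp <- tempfile(fileext = ".yaml")
  write_rule_table(rules_sensitivity(), tmp)
  rt <- read_rule_table(tmp)
  expect_identical(rt, rules_sensitivity())

  shipped <- system.file("extdata", "rules", "default.yaml", package = "dialdep")
  expect_identical(read_rule_table(shipped), rules_default())
  shipped_s <- system.file("extdata", "rules", "sensitivity.yaml", package = "dialdep")
  expect_identical(read_rule_table(shipped_s), rules_sensitivity())
})
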