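test_that("the same config generates byte-identical cohorts", {
  cfg <- preset_dialysis(n = 200, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  # a different seed changes the draw
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(generate_cohort(cfg2)$records, a$records))
})

test_that("the intercept solver hits the 8% target exactly in expectation and under simulation", {
  cfg <- preset_dialysis()
  expect_equal(ms_marginal_prevalence(cfg), 0.08, tolerance = 1e-8)
  # lean Monte-Carlo check of the enumeration: draw only the effect
  # indicators at large n and average the outcome probabilities
  set.seed(7)
  n <- 1e6
  dm <- cfg$demographic_marginals
  eff <- cfg$outcome_model$effects
  p_diab <- sum(dm$ethnicity * c(white_british = 0.30, south_asian = 0.45,
                                 black = 0.18, other = 0.30)[names(dm$ethnicity)])
  lp <- cfg$outcome_model$intercept +
    eff[["cm_diabetes_t2"]] * rbinom(n, 1, p_diab) +
    eff[["le_death_parent_child_spouse"]] * rbinom(n, 1, 0.12) +
    eff[["le_financial_crisis"]] * rbinom(n, 1, 0.15) +
    eff[["education=university_or_apprenticeship"]] *
      rbinom(n, 1, dm$education[["university_or_apprenticeship"]])
  expect_lt(abs(mean(rbinom(n, 1, plogis(lp))) - 0.08), 0.002)
})

test_that("generated symptom profiles recover the true label exactly at zero noise", {
  coh <- generate_cohort(preset_dialysis(n = 2000, seed = 5))
  dx <- classify_cohort(coh$records)
  expect_identical(as.character(dx$category), coh$truth$true_category)
})

test_that("all-zero event prevalences generate no life events", {
  cfg <- preset_dialysis(n = 100, seed = 6)
  cfg$event_prevalences[] <- 0
  coh <- generate_cohort(cfg)
  le <- coh$records[, paste0("le_", dialdep:::life_event_ids)]
  expect_true(all(le == 0))
})

test_that("config validation rejects bad probabilities and unknown effect names", {
  m <- dialdep:::default_marginals()
  m$sex <- c(male = 0.7, female = 0.7)
  expect_error(cohort_config(demographic_marginals = m), "sum to 1")
  cfg <- dialdep:::default_outcome_model()
  cfg$effects <- c(cm_not_a_condition = 1)
  expect_error(cohort_config(outcome_model = cfg), "unknown effect")
  bad_ev <- dialdep:::default_event_prevalences()
  bad_ev[1] <- 1.4
  expect_error(cohort_config(event_prevalences = bad_ev), "\\[0,1\\]")
})

test_that("screening positivity exceeds diagnosed prevalence under the default severity process", {
  coh <- generate_cohort(preset_dialysis(n = 3000, seed = 8))
  dx <- classify_cohort(coh$records)
  scr <- screen_cohort(coh$records, quiet = TRUE)
  dx_prev <- mean(dx$category == "moderate_severe")
  expect_gt(mean(scr$phq2_positive, na.rm = TRUE), dx_prev)
  expect_gt(mean(scr$hamd_positive, na.rm = TRUE), dx_prev)
})

test_that("diagnosed prevalence stays within binomial noise of the 8% target over replicates", {
  # 200 cohorts of n = 300: the replicate-mean prevalence concentrates around
  # 0.08 with standard error sqrt(0.08 * 0.92 / 60000) ~ 0.0011
  prevs <- vapply(1:200, function(s) {
    coh <- generate_cohort(preset_dialysis(n = 300, seed = 1000 + s))
    mean(coh$truth$true_category == "moderate_severe")
  }, numeric(1))
  expect_lt(abs(mean(prevs) - 0.08), 0.005)
})

test_that("symptom noise induces misclassification while zero noise does not", {
  cfg <- preset_dialysis(n = 1000, seed = 9)
  cfg$symptom_noise <- 0.15
  coh <- generate_cohort(cfg)
  dx <- classify_cohort(coh$records)
  expect_gt(mean(as.character(dx$category) != coh$truth$true_category), 0)
})

test_that("cohorts round-trip through the CSV schema", {
  coh <- generate_cohort(preset_dialysis(n = 50, seed = 10))
  tmp <- tempfile(fileext = ".csv")
  paths <- write_cohort(coh, tmp)
  expect_true(all(file.exists(paths)))
  back <- read_participants(paths[["records"]])
  vr <- validate_input(back)
  expect_equal(attr(vr, "n_errors"), 0)
  expect_identical(classify_cohort(back)$category,
                   classify_cohort(coh$records)$category)
})
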