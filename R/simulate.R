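#' Configuration of the synthetic dialysis-cohort generator
#'
#' The generator draws demographics, comorbidities, life events and
#' discrimination items from configurable marginals (with optional
#' ethnicity-specific overrides for comorbidity and discrimination
#' probabilities), assigns the true moderate/severe depression label from a
#' logistic outcome model on named covariate indicators, and then samples the
#' instrument responses — CIS-R symptom profile, PHQ-2 and HAMD-17 items —
#' conditional on a latent depressive-severity process, so that the rule
#' engine recovers the true label exactly (at `symptom_noise = 0`) while the
#' screening instruments over-call relative to the diagnostic reference.
#'
#' Covariates are generated independently except for the configured
#' ethnicity couplings; the generator makes no claim about the unpublished
#' joint distribution of the study covariates.
#'
#' @param n Cohort size.
#' @param seed Integer seed; the same config generates byte-identical output.
#' @param demographic_marginals Named list of category-probability vectors
#'   for sex, ethnicity, education, occupation, marital_status, smoking,
#'   plus scalar `alcohol` probability; each vector must sum to 1.
#' @param age List with `mean`, `sd`, `min`, `max` (years).
#' @param comorbidity_prevalences Named probabilities per condition.
#' @param comorbidity_overrides Named list: condition -> named vector of
#'   per-ethnicity probabilities replacing the base for those groups.
#' @param event_prevalences 12 named probabilities (life events).
#' @param discrimination_prevalences 5 named probabilities.
#' @param discrimination_overrides As `comorbidity_overrides`, for
#'   discrimination items.
#' @param outcome_model List with `intercept` (log-odds; `NA` means solve it
#'   from `target_prevalence` by exact enumeration), `effects` (named
#'   log-odds-ratio vector; names are binary record columns such as
#'   `cm_diabetes_t2` / `le_financial_crisis`, or `variable=level` indicators
#'   such as `education=university_or_apprenticeship`), `target_prevalence`,
#'   and `mild_given_not_ms` (probability a non-case is a mild case).
#' @param latent_severity List controlling instrument generation: per-category
#'   normal means/sds of the latent severity, logistic item-response slopes
#'   and midpoints for HAMD and PHQ-2, and per-category somatic-criterion
#'   probabilities.
#' @param missingness_rates Named per-covariate missing-completely-at-random
#'   rates.
#' @param symptom_noise Per-item flip probability applied to the CIS-R
#'   endorsements after construction; 0 (default) guarantees exact label
#'   recovery by [classify()].
#' @return An object of class `cohort_config`.
#' @seealso [preset_dialysis()], [generate_cohort()]
#' @export
cohort_config <- function(n = 300L,
                          seed = 1L,
                          demographic_marginals = default_marginals(),
                          age = list(mean = 60, sd = 14, min = 18, max = 95),
                          comorbidity_prevalences = default_comorbidity_prevalences(),
                          comorbidity_overrides = default_comorbidity_overrides(),
                          event_prevalences = default_event_prevalences(),
                          discrimination_prevalences = default_discrimination_prevalences(),
                          discrimination_overrides = default_discrimination_overrides(),
                          outcome_model = default_outcome_model(),
                          latent_severity = default_latent_severity(),
                          missingness_rates = default_missingness(),
                          symptom_noise = 0) {
  cfg <- structure(
    list(n = as.integer(n), seed = as.integer(seed),
         demographic_marginals = demographic_marginals, age = age,
         comorbidity_prevalences = comorbidity_prevalences,
         comorbidity_overrides = comorbidity_overrides,
         event_prevalences = event_prevalences,
         discrimination_prevalences = discrimination_prevalences,
         discrimination_overrides = discrimination_overrides,
         outcome_model = outcome_model,
         latent_severity = latent_severity,
         missingness_rates = missingness_rates,
         symptom_noise = symptom_noise),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk_prob <- function(p, what) {
    if (any(p < 0 | p > 1)) stop(what, " probabilities must lie in [0,1]", call. = FALSE)
  }
  for (v in c("sex", "ethnicity", "education", "occupation",
              "marital_status", "smoking")) {
    p <- cfg$demographic_marginals[[v]]
    if (is.null(p)) stop("missing demographic marginal: ", v, call. = FALSE)
    chk_prob(p, v)
    if (abs(sum(p) - 1) > 1e-8) {
      stop("category probabilities for '", v, "' must sum to 1", call. = FALSE)
    }
  }
  chk_prob(cfg$demographic_marginals$alcohol, "alcohol")
  chk_prob(unlist(cfg$comorbidity_prevalences), "comorbidity")
  chk_prob(unlist(cfg$event_prevalences), "life-event")
  chk_prob(unlist(cfg$discrimination_prevalences), "discrimination")
  if (!setequal(names(cfg$event_prevalences), life_event_ids)) {
    stop("event_prevalences must name exactly the 12 life events", call. = FALSE)
  }
  for (nm in names(cfg$outcome_model$effects)) effect_prob(cfg, nm) # validates
  invisible(cfg)
}

default_marginals <- function() {
  list(
    sex = c(male = 0.56, female = 0.44),
    ethnicity = c(white_british = 0.30, south_asian = 0.35,
                  black = 0.25, other = 0.10),
    education = c(none = 0.10, school_incomplete = 0.20,
                  school_complete = 0.40,
                  university_or_apprenticeship = 0.22, other = 0.08),
    occupation = c(unemployed = 0.15, employed = 0.20, retired = 0.45,
                   student = 0.01, housewife = 0.07, off_sick = 0.09,
                   other = 0.03),
    marital_status = c(single = 0.25, married = 0.45,
                       divorced_separated = 0.15, widowed = 0.15),
    smoking = c(never = 0.55, past = 0.30, current = 0.15),
    alcohol = 0.35
  )
}

default_comorbidity_prevalences <- function() {
  c(hypertension = 0.75, diabetes_t1 = 0.05, diabetes_t2 = 0.30,
    obesity = 0.25, cardiovascular = 0.35, cancer = 0.12, copd = 0.08,
    autoimmune = 0.10)
}

default_comorbidity_overrides <- function() {
  list(
    diabetes_t2 = c(south_asian = 0.45, white_british = 0.30, black = 0.18),
    hypertension = c(black = 0.85),
    cancer = c(white_british = 0.18),
    autoimmune = c(white_british = 0.05)
  )
}

default_event_prevalences <- function() {
  c(illness_self = 0.40, illness_relative = 0.25,
    death_parent_child_spouse = 0.12, death_friend_relative = 0.18,
    marital_separation = 0.05, relationship_breakup = 0.06,
    problems_close_person = 0.12, unemployed_seeking = 0.08,
    lost_job = 0.05, financial_crisis = 0.15, police_court = 0.04,
    loss_theft_valued = 0.10)
}

default_discrimination_prevalences <- function() {
  c(unfair_treatment_work = 0.08, job_refusal = 0.06, physical_attack = 0.03,
    property_damage = 0.05, racial_insults = 0.10)
}

default_discrimination_overrides <- function() {
  list(
    racial_insults = c(white_british = 0.03, south_asian = 0.16, black = 0.20),
    unfair_treatment_work = c(white_british = 0.05, south_asian = 0.12,
                              black = 0.14)
  )
}

default_outcome_model <- function() {
  list(
    intercept = NA_real_,            # solved from target_prevalence
    effects = c(
      cm_diabetes_t2 = log(5.32),
      le_death_parent_child_spouse = log(3.62),
      le_financial_crisis = log(3.51),
      "education=university_or_apprenticeship" = log(0.18)
    ),
    target_prevalence = 0.08,
    mild_given_not_ms = 53 / 276
  )
}

default_latent_severity <- function() {
  list(
    mu = c(none = 0, mild = 1.6, moderate_severe = 2.8),
    sd = c(none = 1, mild = 0.7, moderate_severe = 0.7),
    hamd = list(slope = 0.9, mid = 1.75),
    phq2 = list(slope = 1.0, mid = 1.8),
    somatic_p = c(none = 0.15, mild = 0.30, moderate_severe = 0.55)
  )
}

default_missingness <- function() {
  c(education = 0.03, marital_status = 0.02, smoking = 0.02,
    alcohol = 0.02, occupation = 0.03)
}

#' Preset emulating an urban haemodialysis cohort
#'
#' Returns a [cohort_config()] for a 300-person ethnically diverse
#' haemodialysis cohort: 8% marginal prevalence of ICD-10 moderate/severe
#' depression (the intercept is solved numerically from the covariate
#' marginals), with depression odds driven by type 2 diabetes (OR 5.32),
#' death of a spouse, child or parent (OR 3.62), a major financial crisis
#' (OR 3.51) and university-level education (OR 0.18 against completed
#' schooling). All other marginals are the documented package defaults.
#'
#' @param n Cohort size (default 300).
#' @param seed Integer seed.
#' @return A `cohort_config` with the intercept already solved.
#' @export
preset_dialysis <- function(n = 300L, seed = 1L) {
  cfg <- cohort_config(n = n, seed = seed)
  cfg$outcome_model$intercept <- solve_intercept(cfg)
  cfg
}

# ---- outcome-model machinery -----------------------------------------------

# Marginal probability of one effect indicator, mixing over ethnicity where
# overrides apply. Errors on unknown effect names (validation hook).
effect_prob <- function(cfg, name) {
  dm <- cfg$demographic_marginals
  mix_override <- function(base, overrides) {
    eth <- dm$ethnicity
    p <- stats::setNames(rep(base, length(eth)), names(eth))
    if (!is.null(overrides)) p[names(overrides)] <- overrides
    sum(eth * p)
  }
  if (grepl("=", name, fixed = TRUE)) {
    parts <- strsplit(name, "=", fixed = TRUE)[[1]]
    var <- parts[1]; level <- parts[2]
    marg <- dm[[var]]
    if (is.null(marg) || !level %in% names(marg)) {
      stop("unknown effect name: ", name, call. = FALSE)
    }
    return(unname(marg[level]))
  }
  if (startsWith(name, "cm_")) {
    id <- sub("^cm_", "", name)
    if (!id %in% names(cfg$comorbidity_prevalences)) {
      stop("unknown effect name: ", name, call. = FALSE)
    }
    return(mix_override(cfg$comorbidity_prevalences[[id]],
                        cfg$comorbidity_overrides[[id]]))
  }
  if (startsWith(name, "le_")) {
    id <- sub("^le_", "", name)
    if (!id %in% names(cfg$event_prevalences)) {
      stop("unknown effect name: ", name, call. = FALSE)
    }
    return(unname(cfg$event_prevalences[id]))
  }
  if (startsWith(name, "disc_")) {
    id <- sub("^disc_", "", name)
    if (!id %in% names(cfg$discrimination_prevalences)) {
      stop("unknown effect name: ", name, call. = FALSE)
    }
    return(mix_override(cfg$discrimination_prevalences[[id]],
                        cfg$discrimination_overrides[[id]]))
  }
  if (name == "alcohol") return(dm$alcohol)
  stop("unknown effect name: ", name, call. = FALSE)
}

# Effect indicator values on generated records.
effect_indicator <- function(records, name) {
  if (grepl("=", name, fixed = TRUE)) {
    parts <- strsplit(name, "=", fixed = TRUE)[[1]]
    return(as.numeric(records[[parts[1]]] == parts[2]))
  }
  as.numeric(records[[name]])
}

#' Exact marginal prevalence of the simulated diagnosis
#'
#' Enumerates the joint distribution of the outcome-model effect indicators
#' (independent across source variables by construction; ethnicity mixtures
#' folded into comorbidity/discrimination marginals) and returns the exact
#' expected moderate/severe prevalence at a given intercept. This is what the
#' intercept solver inverts — no Monte Carlo involved.
#'
#' @param cfg A `cohort_config`.
#' @param intercept Log-odds intercept; defaults to the configured one.
#' @return Scalar expected prevalence.
#' @export
ms_marginal_prevalence <- function(cfg, intercept = cfg$outcome_model$intercept) {
  eff <- cfg$outcome_model$effects
  # group effects by source variable: same-source categorical levels are
  # mutually exclusive, distinct sources independent
  src <- vapply(names(eff), function(nm) {
    if (grepl("=", nm, fixed = TRUE)) strsplit(nm, "=", fixed = TRUE)[[1]][1] else nm
  }, character(1))
  states <- list()
  for (s in unique(src)) {
    nms <- names(eff)[src == s]
    probs <- vapply(nms, function(nm) effect_prob(cfg, nm), numeric(1))
    if (sum(probs) > 1 + 1e-8) {
      stop("effect indicators on '", s, "' have probabilities summing above 1",
           call. = FALSE)
    }
    states[[s]] <- data.frame(coef = c(eff[nms], 0),
                              prob = c(probs, 1 - sum(probs)))
  }
  grid <- expand.grid(lapply(states, function(st) seq_len(nrow(st))))
  prev <- 0
  for (i in seq_len(nrow(grid))) {
    lp <- intercept
    pr <- 1
    for (j in seq_along(states)) {
      st <- states[[j]][grid[i, j], ]
      lp <- lp + st$coef
      pr <- pr * st$prob
    }
    prev <- prev + pr * stats::plogis(lp)
  }
  prev
}

#' Solve the outcome-model intercept for a target marginal prevalence
#'
#' Root-finds the intercept so that the exact expected moderate/severe
#' prevalence under the configured covariate marginals equals
#' `outcome_model$target_prevalence`.
#'
#' @param cfg A `cohort_config`.
#' @return The intercept (log-odds scale).
#' @export
solve_intercept <- function(cfg) {
  target <- cfg$outcome_model$target_prevalence
  stats::uniroot(function(b0) ms_marginal_prevalence(cfg, b0) - target,
                 interval = c(-15, 5), tol = 1e-10)$root
}

# ---- generation -------------------------------------------------------------

#' Generate a synthetic dialysis cohort
#'
#' Reproducible given the config (seed included). Returns the wide
#' participant table the pipeline consumes plus a ground-truth sidecar with
#' the latent labels and linear predictors for recovery tests.
#'
#' @param cfg A [cohort_config()]; the intercept must be set (use
#'   [preset_dialysis()] or [solve_intercept()]).
#' @return List of class `synthetic_cohort` with `records` (wide
#'   `data.frame`, one row per participant) and `truth` (`participant_id`,
#'   `true_category`, `linear_predictor`, `p_ms`, `latent_severity`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (is.na(cfg$outcome_model$intercept)) {
    cfg$outcome_model$intercept <- solve_intercept(cfg)
  }
  n <- cfg$n
  dm <- cfg$demographic_marginals
  set.seed(cfg$seed)

  draw_cat <- function(p) names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
  rec <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    age = pmin(pmax(round(stats::rnorm(n, cfg$age$mean, cfg$age$sd)),
                    cfg$age$min), cfg$age$max),
    sex = draw_cat(dm$sex),
    ethnicity = draw_cat(dm$ethnicity),
    education = draw_cat(dm$education),
    occupation = draw_cat(dm$occupation),
    marital_status = draw_cat(dm$marital_status),
    smoking = draw_cat(dm$smoking),
    alcohol = stats::rbinom(n, 1, dm$alcohol),
    stringsAsFactors = FALSE
  )

  with_override <- function(base, overrides) {
    p <- rep(base, n)
    if (!is.null(overrides)) {
      for (e in names(overrides)) p[rec$ethnicity == e] <- overrides[[e]]
    }
    p
  }
  for (cm in names(cfg$comorbidity_prevalences)) {
    rec[[paste0("cm_", cm)]] <- stats::rbinom(
      n, 1, with_override(cfg$comorbidity_prevalences[[cm]],
                          cfg$comorbidity_overrides[[cm]]))
  }
  for (ev in life_event_ids) {
    rec[[paste0("le_", ev)]] <- stats::rbinom(n, 1, cfg$event_prevalences[[ev]])
  }
  for (d in discrimination_ids) {
    rec[[paste0("disc_", d)]] <- stats::rbinom(
      n, 1, with_override(cfg$discrimination_prevalences[[d]],
                          cfg$discrimination_overrides[[d]]))
  }

  # true diagnosis label from the logistic outcome model
  eff <- cfg$outcome_model$effects
  lp <- rep(cfg$outcome_model$intercept, n)
  for (nm in names(eff)) lp <- lp + eff[[nm]] * effect_indicator(rec, nm)
  p_ms <- stats::plogis(lp)
  ms <- stats::rbinom(n, 1, p_ms) == 1
  mild <- !ms & stats::rbinom(n, 1, cfg$outcome_model$mild_given_not_ms) == 1
  category <- ifelse(ms, "moderate_severe", ifelse(mild, "mild", "none"))

  sym <- sample_symptom_profiles(category, cfg$symptom_noise)
  rec <- cbind(rec, sym)

  ls <- cfg$latent_severity
  z <- stats::rnorm(n, ls$mu[category], ls$sd[category])
  som_k <- stats::rbinom(n, length(somatic_flag_ids), ls$somatic_p[category])
  som <- matrix(0L, n, length(somatic_flag_ids),
                dimnames = list(NULL, paste0("som_", somatic_flag_ids)))
  for (i in seq_len(n)) {
    if (som_k[i] > 0) som[i, sample.int(ncol(som), som_k[i])] <- 1L
  }
  rec <- cbind(rec, as.data.frame(som))

  p_phq <- stats::plogis(ls$phq2$slope * (z - ls$phq2$mid))
  rec$phq2_1 <- stats::rbinom(n, 3, p_phq)
  rec$phq2_2 <- stats::rbinom(n, 3, p_phq)
  p_ham <- stats::plogis(ls$hamd$slope * (z - ls$hamd$mid))
  for (k in 1:17) {
    rec[[paste0("hamd_", k)]] <- stats::rbinom(n, hamd_item_max[k], p_ham)
  }

  for (v in names(cfg$missingness_rates)) {
    miss <- stats::runif(n) < cfg$missingness_rates[[v]]
    rec[[v]][miss] <- NA
  }

  rec <- rec[, participant_columns()]
  truth <- data.frame(
    participant_id = rec$participant_id,
    true_category = category,
    linear_predictor = lp,
    p_ms = p_ms,
    latent_severity = z,
    stringsAsFactors = FALSE
  )
  structure(list(records = rec, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

# Sample CIS-R endorsements + duration consistent with each true category
# under the default rule table: none => at most 3 total symptoms; mild =>
# episode with 4-5 total; moderate_severe => episode with 6+ total.
sample_symptom_profiles <- function(category, noise = 0) {
  n <- length(category)
  admin <- c(cisr_core_items, cisr_additional_items)
  M <- matrix(0L, n, length(admin), dimnames = list(NULL, paste0("cisr_", admin)))
  duration <- numeric(n)
  for (i in seq_len(n)) {
    cat_i <- category[i]
    if (cat_i == "none") {
      t <- sample(0:3, 1, prob = c(0.35, 0.30, 0.20, 0.15))
      duration[i] <- sample(c(0, 1, 2, 4, 8), 1, prob = c(0.3, 0.2, 0.2, 0.2, 0.1))
      if (t > 0) M[i, sample.int(9, t)] <- 1L
      next
    }
    if (cat_i == "mild") {
      core <- sample(2:3, 1, prob = c(0.6, 0.4))
      total <- sample(4:5, 1, prob = c(0.6, 0.4))
      duration[i] <- sample(c(2, 4, 8, 12), 1, prob = c(0.3, 0.3, 0.25, 0.15))
    } else {
      core <- sample(2:3, 1, prob = c(0.3, 0.7))
      total <- if (core == 2) {
        sample(6:8, 1, prob = c(0.5, 0.3, 0.2))
      } else {
        sample(6:9, 1, prob = c(0.4, 0.3, 0.2, 0.1))
      }
      duration[i] <- sample(c(4, 8, 12, 26), 1, prob = c(0.3, 0.3, 0.2, 0.2))
    }
    M[i, sample.int(3, core)] <- 1L
    M[i, 3 + sample.int(6, total - core)] <- 1L
  }
  if (noise > 0) {
    flips <- matrix(stats::runif(n * 9) < noise, n, 9)
    M <- abs(M - flips * 1L)
    storage.mode(M) <- "integer"
  }
  out <- as.data.frame(M)
  out$cisr_duration_weeks <- duration
  out
}

#' Write a synthetic cohort to CSV
#'
#' Emits the participant table in the schema [validate_input()] checks and
#' the ground truth as a sidecar CSV.
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output CSV path for the records; the truth sidecar gets the
#'   suffix `_truth.csv`.
#' @return Invisibly, the two paths written.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  utils::write.csv(cohort$records, path, row.names = FALSE, na = "")
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  if (identical(truth_path, path)) truth_path <- paste0(path, "_truth.csv")
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE)
  invisible(c(records = path, truth = truth_path))
}
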