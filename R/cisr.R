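#' Build a CIS-R depression-section symptom profile
#'
#' A profile records binary endorsements of the nine administered symptom
#' items, optional values for the three items excluded under the dialysis
#' protocol (appetite change, weight change, impairment — representable but
#' unset by default), the episode duration in weeks, and the set of endorsed
#' somatic-syndrome criteria.
#'
#' @param depressed_mood,loss_of_interest,fatigue Core symptoms.
#' @param concentration,self_esteem_low,guilt,pessimism_or_suicidality,sleep_disturbance,agitation_or_retardation
#'   Additional symptoms.
#' @param appetite_change,weight_change,impairment Items not administered
#'   under the default protocol; leave `NA` unless recorded.
#' @param duration_weeks Episode duration, weeks (>= 0).
#' @param somatic_flags Character vector of endorsed somatic criteria, a
#'   subset of: diurnal_variation, early_waking, loss_of_reactivity,
#'   libido_loss, psychomotor_change.
#'
#' @return An object of class `symptom_profile`.
#' @examples
#' symptom_profile(depressed_mood = TRUE, loss_of_interest = TRUE,
#'                 concentration = TRUE, sleep_disturbance = TRUE,
#'                 duration_weeks = 4)
#' @export
symptom_profile <- function(depressed_mood = FALSE, loss_of_interest = FALSE,
                            fatigue = FALSE, concentration = FALSE,
                            self_esteem_low = FALSE, guilt = FALSE,
                            pessimism_or_suicidality = FALSE,
                            sleep_disturbance = FALSE,
                            agitation_or_retardation = FALSE,
                            appetite_change = NA, weight_change = NA,
                            impairment = NA, duration_weeks = 0,
                            somatic_flags = character()) {
  items <- list(
    depressed_mood = depressed_mood, loss_of_interest = loss_of_interest,
    fatigue = fatigue, concentration = concentration,
    self_esteem_low = self_esteem_low, guilt = guilt,
    pessimism_or_suicidality = pessimism_or_suicidality,
    sleep_disturbance = sleep_disturbance,
    agitation_or_retardation = agitation_or_retardation,
    appetite_change = appetite_change, weight_change = weight_change,
    impairment = impairment
  )
  for (nm in names(items)) {
    v <- items[[nm]]
    if (length(v) != 1 || (!is.logical(v) && !v %in% c(0, 1))) {
      stop("item '", nm, "' must be a single logical (or 0/1) value",
           call. = FALSE)
    }
    items[[nm]] <- as.logical(v)
  }
  if (!is.numeric(duration_weeks) || length(duration_weeks) != 1 ||
      is.na(duration_weeks) || duration_weeks < 0) {
    stop("duration_weeks must be a single non-negative number", call. = FALSE)
  }
  somatic_flags <- unique(as.character(somatic_flags))
  bad <- setdiff(somatic_flags, somatic_flag_ids)
  if (length(bad) > 0) {
    stop("unknown somatic flag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    c(items, list(duration_weeks = as.numeric(duration_weeks),
                  somatic_flags = somatic_flags)),
    class = "symptom_profile"
  )
}

#' Classify a symptom profile into an ICD-10 depressive-episode category
#'
#' Applies the rule table to one profile. Items in `rules$excluded_items` are
#' ignored under `as_administered` (their stored values, set or unset, never
#' influence the result) and counted as endorsed for every participant under
#' `impute_present`. An episode requires the minimum duration, the minimum
#' core-symptom count and a total within or above the mild band; the mild and
#' moderate bands and the severe floor then grade severity, with moderate and
#' severe collapsed into the reported `moderate_severe` category. The somatic
#' syndrome is qualified only for diagnosed episodes.
#'
#' @param profile A [symptom_profile()].
#' @param rules A [rule_table()].
#' @return An object of class `depression_diagnosis`: a list with `category`
#'   (factor: none < mild < moderate_severe), `severe_subflag`,
#'   `somatic_syndrome`, `core_count`, `additional_count`, `total_count`.
#' @export
classify <- function(profile, rules = rules_default()) {
  stopifnot(inherits(profile, "symptom_profile"), inherits(rules, "rule_table"))

  endorsed <- function(item) {
    if (item %in% rules$excluded_items) {
      return(rules$imputation_mode == "impute_present")
    }
    isTRUE(profile[[item]])
  }
  core_count <- sum(vapply(cisr_core_items, endorsed, logical(1)))
  additional_count <- sum(vapply(
    c(cisr_additional_items, cisr_excludable_items), endorsed, logical(1)
  ))
  total <- core_count + additional_count

  episode <- profile$duration_weeks >= rules$min_duration_weeks &&
    core_count >= rules$min_core_for_episode &&
    total >= rules$mild_total_range[1]

  severe_subflag <- FALSE
  if (!episode) {
    category <- "none"
  } else if (total <= rules$mild_total_range[2]) {
    category <- "mild"
  } else {
    category <- "moderate_severe"
    severe_subflag <- total >= rules$severe_min_total &&
      (!rules$severe_requires_all_core || core_count == 3L)
  }

  somatic <- category != "none" &&
    length(profile$somatic_flags) >= rules$somatic_min_count

  structure(
    list(
      category = factor(category, levels = c("none", "mild", "moderate_severe"),
                        ordered = TRUE),
      severe_subflag = severe_subflag,
      somatic_syndrome = somatic,
      core_count = as.integer(core_count),
      additional_count = as.integer(additional_count),
      total_count = as.integer(total)
    ),
    class = "depression_diagnosis"
  )
}

#' @export
print.depression_diagnosis <- function(x, ...) {
  cat(sprintf("ICD-10 depressive episode: %s%s%s (core %d + additional %d = %d)\n",
              as.character(x$category),
              if (x$severe_subflag) " [severe]" else "",
              if (x$somatic_syndrome) " with somatic syndrome" else "",
              x$core_count, x$additional_count, x$total_count))
  invisible(x)
}

#' Materialise the sensitivity imputation on a profile
#'
#' Returns a copy of the profile with every item in `rules$excluded_items`
#' set to endorsed, all other fields unchanged. This makes the post hoc
#' sensitivity analysis explicit: classifying the returned profile under
#' `impute_present` rules is identical to classifying the original.
#'
#' @inheritParams classify
#' @return A `symptom_profile`.
#' @export
apply_sensitivity <- function(profile, rules = rules_sensitivity()) {
  stopifnot(inherits(profile, "symptom_profile"), inherits(rules, "rule_table"))
  if (rules$imputation_mode != "impute_present") {
    stop("apply_sensitivity() requires rules with imputation_mode = 'impute_present'",
         call. = FALSE)
  }
  for (item in rules$excluded_items) profile[[item]] <- TRUE
  profile
}

#' Classify every profile in a cohort
#'
#' @param profiles A list of [symptom_profile()] objects, or a wide
#'   participant `data.frame` with `cisr_*`, `cisr_duration_weeks` and
#'   `som_*` columns (as produced by [generate_cohort()]).
#' @param rules A [rule_table()].
#' @return A `data.frame` with one row per participant: `category`,
#'   `severe_subflag`, `somatic_syndrome`, `core_count`, `additional_count`,
#'   `total_count`.
#' @export
classify_cohort <- function(profiles, rules = rules_default()) {
  if (is.data.frame(profiles)) return(classify_records(profiles, rules))
  if (length(profiles) == 0) stop("empty cohort", call. = FALSE)
  rows <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    dx <- tryCatch(
      classify(profiles[[i]], rules),
      error = function(e) {
        stop("participant ", i, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    rows[[i]] <- data.frame(
      category = as.character(dx$category),
      severe_subflag = dx$severe_subflag,
      somatic_syndrome = dx$somatic_syndrome,
      core_count = dx$core_count,
      additional_count = dx$additional_count,
      total_count = dx$total_count,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$category <- factor(out$category,
                         levels = c("none", "mild", "moderate_severe"),
                         ordered = TRUE)
  rownames(out) <- NULL
  out
}

# Vectorized classification over the wide participant table; same rule
# semantics as classify() (a consistency property in the test suite holds the
# two paths together).
classify_records <- function(records, rules) {
  if (nrow(records) == 0) stop("empty cohort", call. = FALSE)
  need <- c(paste0("cisr_", c(cisr_core_items, cisr_additional_items)),
            "cisr_duration_weeks", paste0("som_", somatic_flag_ids))
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop("participant table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(records)
  if (any(is.na(records$cisr_duration_weeks)) ||
      any(records$cisr_duration_weeks < 0)) {
    bad <- which(is.na(records$cisr_duration_weeks) |
                   records$cisr_duration_weeks < 0)[1]
    stop("participant ", bad, ": duration_weeks must be a single non-negative number",
         call. = FALSE)
  }
  item_col <- function(item) {
    imputed <- item %in% rules$excluded_items
    if (imputed) {
      return(rep(as.numeric(rules$imputation_mode == "impute_present"), n))
    }
    cn <- paste0("cisr_", item)
    if (cn %in% names(records)) {
      v <- as.numeric(records[[cn]] %in% c(1, TRUE))
      return(v)
    }
    rep(0, n)  # representable-but-unset items
  }
  core <- Reduce(`+`, lapply(cisr_core_items, item_col))
  additional <- Reduce(`+`, lapply(c(cisr_additional_items, cisr_excludable_items),
                                   item_col))
  total <- core + additional
  duration <- records$cisr_duration_weeks
  som_count <- Reduce(`+`, lapply(paste0("som_", somatic_flag_ids), function(cn) {
    as.numeric(records[[cn]] %in% c(1, TRUE))
  }))

  episode <- duration >= rules$min_duration_weeks &
    core >= rules$min_core_for_episode &
    total >= rules$mild_total_range[1]
  category <- ifelse(!episode, "none",
                     ifelse(total <= rules$mild_total_range[2], "mild",
                            "moderate_severe"))
  severe <- category == "moderate_severe" & total >= rules$severe_min_total &
    (!rules$severe_requires_all_core | core == 3)
  data.frame(
    category = factor(category, levels = c("none", "mild", "moderate_severe"),
                      ordered = TRUE),
    severe_subflag = severe,
    somatic_syndrome = category != "none" & som_count >= rules$somatic_min_count,
    core_count = as.integer(core),
    additional_count = as.integer(additional),
    total_count = as.integer(total)
  )
}

# Convert wide participant rows into symptom_profile objects.
profiles_from_records <- function(records) {
  admin <- c(cisr_core_items, cisr_additional_items)
  need <- c(paste0("cisr_", admin), "cisr_duration_weeks",
            paste0("som_", somatic_flag_ids))
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop("participant table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(records)), function(i) {
    args <- stats::setNames(
      lapply(admin, function(it) isTRUE(records[[paste0("cisr_", it)]][i] == 1) ||
               isTRUE(records[[paste0("cisr_", it)]][i])),
      admin
    )
    flags <- somatic_flag_ids[vapply(
      somatic_flag_ids,
      function(f) isTRUE(records[[paste0("som_", f)]][i] == 1) ||
        isTRUE(records[[paste0("som_", f)]][i]),
      logical(1)
    )]
    args$duration_weeks <- records$cisr_duration_weeks[i]
    args$somatic_flags <- flags
    do.call(symptom_profile, args)
  })
}
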