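#' Declarative rule table for ICD-10 depressive-episode classification
#'
#' The classification algorithm is data-driven: every threshold lives in a
#' rule table rather than in code, so a different operationalisation of the
#' ICD-10 F32 criteria (for example one with the full appetite/weight/
#' impairment item set) can be dropped in without touching the engine.
#'
#' The default table follows the CIS-R / Adult Psychiatric Morbidity Survey
#' operationalisation of ICD-10 F32: an episode requires duration of at least
#' two weeks and at least two of the three core symptoms (depressed mood,
#' loss of interest, fatigue); 4-5 total symptoms grade mild, 6-7 moderate,
#' and 8 or more with all three core symptoms severe. Moderate and severe are
#' collapsed into one reporting band (`moderate_severe`), with a traceability
#' sub-flag marking severe. Because the appetite, weight and impairment items
#' are excluded under the dialysis administration protocol, the somatic
#' syndrome is called on at least 3 of the 5 remaining somatic criteria.
#'
#' @param min_core_for_episode Minimum number of core symptoms (2 or 3).
#' @param mild_total_range Integer length-2 vector, inclusive total-symptom
#'   band for mild episodes.
#' @param moderate_total_range Integer length-2 vector for moderate episodes.
#' @param severe_min_total Minimum total symptoms for a severe episode.
#' @param severe_requires_all_core Must all three core symptoms be present
#'   for the severe grade?
#' @param min_duration_weeks Minimum episode duration in weeks.
#' @param somatic_min_count Minimum somatic criteria for the somatic-syndrome
#'   qualifier.
#' @param excluded_items Items not administered (and therefore ignored)
#'   under the protocol; must be symptom identifiers known to the engine.
#' @param imputation_mode `"as_administered"` scores only administered items;
#'   `"impute_present"` counts every excluded item as endorsed (the
#'   sensitivity analysis).
#'
#' @return An object of class `rule_table`.
#' @seealso [classify()], [rules_default()], [rules_sensitivity()]
#' @export
rule_table <- function(min_core_for_episode = 2L,
                       mild_total_range = c(4L, 5L),
                       moderate_total_range = c(6L, 7L),
                       severe_min_total = 8L,
                       severe_requires_all_core = TRUE,
                       min_duration_weeks = 2,
                       somatic_min_count = 3L,
                       excluded_items = cisr_excludable_items,
                       imputation_mode = c("as_administered", "impute_present")) {
  imputation_mode <- match.arg(imputation_mode)
  excluded_items <- as.character(excluded_items)
  unknown <- setdiff(excluded_items, cisr_all_items)
  if (length(unknown) > 0) {
    stop("unknown item identifier(s) in excluded_items: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!min_core_for_episode %in% 2:3) {
    stop("min_core_for_episode must be 2 or 3", call. = FALSE)
  }
  mild_total_range <- as.integer(mild_total_range)
  moderate_total_range <- as.integer(moderate_total_range)
  severe_min_total <- as.integer(severe_min_total)
  if (mild_total_range[2] >= moderate_total_range[1] ||
      moderate_total_range[2] >= severe_min_total) {
    stop("severity bands must be disjoint and ordered (mild < moderate < severe)",
         call. = FALSE)
  }
  structure(
    list(
      min_core_for_episode = as.integer(min_core_for_episode),
      mild_total_range = mild_total_range,
      moderate_total_range = moderate_total_range,
      severe_min_total = severe_min_total,
      severe_requires_all_core = isTRUE(severe_requires_all_core),
      min_duration_weeks = as.numeric(min_duration_weeks),
      somatic_min_count = as.integer(somatic_min_count),
      excluded_items = excluded_items,
      imputation_mode = imputation_mode
    ),
    class = "rule_table"
  )
}

#' Shipped rule-table presets
#'
#' `rules_default()` is the study protocol: appetite, weight and impairment
#' excluded and ignored. `rules_sensitivity()` is the post hoc sensitivity
#' variant in which every excluded item is imputed as present for every
#' participant.
#'
#' @return A `rule_table`.
#' @export
rules_default <- function() rule_table()

#' @rdname rules_default
#' @export
rules_sensitivity <- function() rule_table(imputation_mode = "impute_present")

#' Read or write a rule table as YAML
#'
#' @param path File path.
#' @return `read_rule_table()` returns a validated `rule_table`;
#'   `write_rule_table()` returns `path` invisibly.
#' @export
read_rule_table <- function(path) {
  raw <- yaml::read_yaml(path)
  needed <- c("min_core_for_episode", "mild_total_range", "moderate_total_range",
              "severe_min_total", "severe_requires_all_core",
              "min_duration_weeks", "somatic_min_count",
              "excluded_items", "imputation_mode")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("rule-table config is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(rule_table, raw[needed])
}

#' @rdname read_rule_table
#' @param rules A `rule_table`.
#' @export
write_rule_table <- function(rules, path) {
  stopifnot(inherits(rules, "rule_table"))
  yaml::write_yaml(unclass(rules), path)
  invisible(path)
}

#' @export
print.rule_table <- function(x, ...) {
  cat("ICD-10 depressive-episode rule table\n")
  cat(sprintf("  episode: >= %d core symptoms, duration >= %g weeks\n",
              x$min_core_for_episode, x$min_duration_weeks))
  cat(sprintf("  bands: mild %d-%d, moderate %d-%d, severe >= %d%s\n",
              x$mild_total_range[1], x$mild_total_range[2],
              x$moderate_total_range[1], x$moderate_total_range[2],
              x$severe_min_total,
              if (x$severe_requires_all_core) " (all core)" else ""))
  cat(sprintf("  somatic syndrome: >= %d of %d criteria\n",
              x$somatic_min_count, length(somatic_flag_ids)))
  cat(sprintf("  excluded items [%s]: %s\n", x$imputation_mode,
              paste(x$excluded_items, collapse = ", ")))
  invisible(x)
}
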