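#' Read a wide participant CSV
#'
#' Reads the participant schema with blank cells as missing values (the
#' convention [write_cohort()] writes).
#'
#' @param path CSV path.
#' @return `data.frame`.
#' @export
read_participants <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Validate a wide participant table
#'
#' Schema, range and category-level checks for the participant CSV. Any
#' error blocks the analysis pipeline; the report carries one row per
#' problem with the offending row and column.
#'
#' @param x Path to a CSV file, or a `data.frame`.
#' @return `data.frame` with columns `row`, `column`, `problem`; attribute
#'   `n_errors` holds the error count (0 means valid).
#' @export
validate_input <- function(x) {
  records <- if (is.character(x)) read_participants(x) else x
  probs <- list()
  add <- function(row, column, problem) {
    probs[[length(probs) + 1]] <<- data.frame(
      row = row, column = column, problem = problem, stringsAsFactors = FALSE)
  }

  missing_cols <- setdiff(participant_columns(), names(records))
  for (mc in missing_cols) add(NA_integer_, mc, "missing column")

  chk_level <- function(col, levels) {
    if (!col %in% names(records)) return()
    v <- as.character(records[[col]])
    bad <- which(!is.na(v) & v != "" & !v %in% levels)
    for (i in bad) {
      add(i, col, paste0("unknown level '", v[i], "' (expected one of: ",
                         paste(levels, collapse = ", "), ")"))
    }
  }
  chk_range <- function(col, lo, hi, integer = TRUE) {
    if (!col %in% names(records)) return()
    v <- suppressWarnings(as.numeric(records[[col]]))
    bad <- which(!is.na(records[[col]]) &
                   (is.na(v) | v < lo | v > hi | (integer & v != round(v))))
    for (i in bad) add(i, col, sprintf("value out of range [%g, %g]", lo, hi))
  }

  chk_range("age", 1, 120)
  chk_level("sex", sex_levels)
  chk_level("ethnicity", ethnicity_levels)
  chk_level("education", education_levels)
  chk_level("occupation", occupation_levels)
  chk_level("marital_status", marital_levels)
  chk_level("smoking", smoking_levels)
  binary_cols <- c("alcohol", paste0("le_", life_event_ids),
                   paste0("disc_", discrimination_ids),
                   paste0("cm_", comorbidity_ids),
                   paste0("cisr_", c(cisr_core_items, cisr_additional_items)),
                   paste0("som_", somatic_flag_ids))
  for (bc in binary_cols) chk_range(bc, 0, 1)
  chk_range("cisr_duration_weeks", 0, Inf, integer = FALSE)
  for (k in 1:2) chk_range(paste0("phq2_", k), 0, 3)
  for (k in 1:17) chk_range(paste0("hamd_", k), 0, hamd_item_max[k])

  out <- if (length(probs) > 0) {
    do.call(rbind, probs)
  } else {
    data.frame(row = integer(), column = character(), problem = character(),
               stringsAsFactors = FALSE)
  }
  attr(out, "n_errors") <- nrow(out)
  out
}

# Cross-tabulated descriptive table (counts, percentages to 1 dp, and the
# chi-squared/Fisher p-value from the switching rule). Continuous variables
# are summarised as mean (sd) per stratum without a test.
descriptive_table <- function(records, vars, by) {
  strata <- known_levels(by) %||% sort(unique(as.character(records[[by]])))
  svec <- as.character(records[[by]])
  rows <- list()
  for (v in vars) {
    col <- records[[v]]
    if (is.numeric(col) && length(unique(stats::na.omit(col))) > 10) {
      vals <- vapply(c(list(rep(TRUE, nrow(records))),
                       lapply(strata, function(s) !is.na(svec) & svec == s)),
                     function(idx) sprintf("%.1f (%.1f)",
                                           mean(col[idx], na.rm = TRUE),
                                           stats::sd(col[idx], na.rm = TRUE)),
                     character(1))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = "mean (sd)",
        overall = vals[1],
        stats::setNames(as.data.frame(t(vals[-1]), stringsAsFactors = FALSE),
                        strata),
        p_value = NA_real_, test = NA_character_,
        stringsAsFactors = FALSE, check.names = FALSE)
      next
    }
    vch <- if (is.numeric(col)) as.character(col) else as.character(col)
    lev <- known_levels(v) %||% sort(unique(stats::na.omit(vch)))
    ok <- !is.na(vch) & !is.na(svec)
    tab <- table(factor(vch[ok], levels = lev), factor(svec[ok], levels = strata))
    p <- NA_real_; method <- NA_character_
    keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
    tt <- tab[keep_r, keep_c, drop = FALSE]
    if (nrow(tt) >= 2 && ncol(tt) >= 2) {
      ct <- contingency_test(tt)
      p <- ct$p_value; method <- ct$method
    }
    denom_all <- sum(tab)
    denom_s <- colSums(tab)
    for (l in lev) {
      cnt <- tab[l, ]
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = l,
        overall = sprintf("%d (%.1f%%)", sum(cnt),
                          100 * sum(cnt) / max(denom_all, 1)),
        stats::setNames(as.data.frame(t(sprintf(
          "%d (%.1f%%)", cnt, 100 * cnt / pmax(denom_s, 1))),
          stringsAsFactors = FALSE), strata),
        p_value = p, test = method,
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the analysis frame
#'
#' Classifies the cohort under a rule table, scores both screening
#' instruments, and returns the records with `icd10_category`,
#' `icd10_somatic`, screening scores and positivity appended.
#'
#' @param records Wide participant `data.frame`.
#' @param rules A [rule_table()].
#' @return The augmented `data.frame`.
#' @export
annotate_cohort <- function(records, rules = rules_default()) {
  dx <- classify_cohort(records, rules)
  scr <- screen_cohort(records, quiet = TRUE)
  records$icd10_category <- dx$category
  records$icd10_severe_subflag <- dx$severe_subflag
  records$icd10_somatic <- dx$somatic_syndrome
  cbind(records, scr)
}

#' Run the full analysis pipeline
#'
#' End-to-end reproduction of the study workflow on a participant table:
#' validation, ICD-10 classification (default and sensitivity rule tables),
#' screening scores, descriptive tables by sex and by ethnicity, prevalence
#' estimates with exact intervals for each depression definition, per-block
#' backward stepwise screening at the retention threshold, the final
#' multivariable model (age and sex always included), and a
#' default-versus-sensitivity comparison. Every table is written as CSV with
#' a JSON manifest of run metadata; nothing is written if validation fails.
#'
#' @param input Path to a participant CSV, or a `data.frame`.
#' @param out_dir Output directory (created if needed). `NULL` skips writing
#'   and returns the result bundle only.
#' @param rules Default rule table (object or YAML path).
#' @param sensitivity_rules Sensitivity rule table (object or YAML path).
#' @param retention_threshold Stepwise retention threshold (default 0.1).
#' @param sig_level Final-model significance flag level (default 0.05).
#' @param ci_level Confidence level for intervals.
#' @param separation_policy Passed to the model fits.
#' @param seed Recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters when `input` was simulated).
#' @param verbose Log sample sizes at each filtering step.
#' @return Invisibly, a list with every table, the stepwise traces, the
#'   final model and the manifest.
#' @export
run_full_pipeline <- function(input, out_dir = NULL,
                              rules = rules_default(),
                              sensitivity_rules = rules_sensitivity(),
                              retention_threshold = 0.1,
                              sig_level = 0.05, ci_level = 0.95,
                              separation_policy = "flag",
                              seed = NA_integer_, verbose = FALSE) {
  if (is.character(rules)) rules <- read_rule_table(rules)
  if (is.character(sensitivity_rules)) {
    sensitivity_rules <- read_rule_table(sensitivity_rules)
  }
  records <- if (is.character(input)) read_participants(input) else input
  vr <- validate_input(records)
  if (attr(vr, "n_errors") > 0) {
    stop("input validation failed with ", attr(vr, "n_errors"),
         " error(s); first: row ", vr$row[1], ", column ", vr$column[1],
         ": ", vr$problem[1], call. = FALSE)
  }
  n <- nrow(records)
  say <- function(...) if (verbose) message(sprintf(...))
  say("pipeline: n = %d validated records", n)

  ann <- annotate_cohort(records, rules)
  dx_sens <- classify_cohort(records, sensitivity_rules)

  # (a)/(b) descriptive tables
  demo_vars <- c("age", "sex", "ethnicity", "education", "occupation",
                 "marital_status", "smoking", "alcohol",
                 paste0("le_", life_event_ids),
                 paste0("disc_", discrimination_ids))
  health_vars <- c("icd10_category", "phq2_positive", "hamd_positive",
                   paste0("cm_", comorbidity_ids))
  ann2 <- ann
  ann2$icd10_category <- as.character(ann2$icd10_category)
  tab_sex <- descriptive_table(ann2, setdiff(demo_vars, "sex"), by = "sex")
  tab_sex_health <- descriptive_table(ann2, health_vars, by = "sex")
  tab_eth <- descriptive_table(ann2, setdiff(demo_vars, "ethnicity"),
                               by = "ethnicity")
  tab_eth_health <- descriptive_table(ann2, health_vars, by = "ethnicity")
  descriptive_by_sex <- rbind(
    cbind(section = "demographics", tab_sex),
    cbind(section = "health", tab_sex_health))
  descriptive_by_ethnicity <- rbind(
    cbind(section = "demographics", tab_eth),
    cbind(section = "health", tab_eth_health))

  # (c) prevalence of each depression definition
  defs <- list(
    icd10_mild = ann$icd10_category == "mild",
    icd10_moderate_severe = ann$icd10_category == "moderate_severe",
    phq2_positive = ann$phq2_positive,
    hamd_positive = ann$hamd_positive
  )
  prev_tab <- do.call(rbind, lapply(names(defs), function(d) {
    v <- defs[[d]]
    est <- prevalence(sum(v, na.rm = TRUE), sum(!is.na(v)), level = ci_level)
    data.frame(definition = d, count = est$count, n = est$n,
               percent = round(100 * est$proportion, 1),
               ci_low = round(100 * est$ci_low, 1),
               ci_high = round(100 * est$ci_high, 1),
               stringsAsFactors = FALSE)
  }))

  # (d) per-block stepwise screening
  outcome <- ann$icd10_category == "moderate_severe"
  blocks <- block_specs()
  traces <- list()
  retained_specs <- list()
  all_specs <- unlist(blocks, recursive = FALSE)
  names(all_specs) <- vapply(all_specs, `[[`, character(1), "name")
  for (b in names(blocks)) {
    dm <- build_design_matrix(records, blocks[[b]], outcome = outcome)
    say("pipeline: block '%s' complete-case n = %d of %d", b, dm$n_used, n)
    traces[[b]] <- backward_stepwise(dm$X, dm$y,
                                     threshold = retention_threshold,
                                     groups = dm$groups,
                                     complete = dm$complete,
                                     separation_policy = separation_policy)
  }
  trace_tab <- do.call(rbind, lapply(names(traces), function(b) {
    tr <- traces[[b]]
    rbind(
      if (nrow(tr$removal_sequence) > 0) {
        data.frame(block = b, variable = tr$removal_sequence$variable,
                   action = "removed",
                   p_value = tr$removal_sequence$p_at_removal,
                   step = tr$removal_sequence$step, stringsAsFactors = FALSE)
      },
      if (length(tr$retained) > 0) {
        data.frame(block = b, variable = names(tr$retained),
                   action = "retained", p_value = unname(tr$retained),
                   step = NA_integer_, stringsAsFactors = FALSE)
      }
    )
  }))

  # (e) final model: block-retained variables plus age and sex
  retained_vars <- unique(c(unlist(lapply(traces, function(tr) names(tr$retained)),
                                   use.names = FALSE), "age", "sex"))
  final_specs <- all_specs[retained_vars]
  dmf <- build_design_matrix(records, final_specs, outcome = outcome)
  say("pipeline: final model complete-case n = %d of %d", dmf$n_used, n)
  final <- fit_final_model(dmf$X, dmf$y, complete = dmf$complete,
                           level = ci_level, sig_level = sig_level,
                           separation_policy = separation_policy)
  final_tab <- final$terms
  final_tab$odds_ratio <- round(final_tab$odds_ratio, 2)
  final_tab$ci_low <- round(final_tab$ci_low, 2)
  final_tab$ci_high <- round(final_tab$ci_high, 2)

  # (f) sensitivity comparison
  sens_tab <- data.frame(
    category = c("none", "mild", "moderate_severe"),
    as_administered = as.integer(table(ann$icd10_category)),
    impute_present = as.integer(table(dx_sens$category)),
    stringsAsFactors = FALSE
  )

  result <- list(
    descriptive_by_sex = descriptive_by_sex,
    descriptive_by_ethnicity = descriptive_by_ethnicity,
    prevalence = prev_tab,
    stepwise_trace = trace_tab,
    final_model = final_tab,
    sensitivity_comparison = sens_tab,
    final_fit = final,
    traces = traces
  )

  if (!is.null(out_dir)) {
    result$manifest <- write_report_bundle(result, out_dir, seed = seed,
                                           config = list(
                                             rules = unclass(rules),
                                             sensitivity_rules = unclass(sensitivity_rules),
                                             retention_threshold = retention_threshold,
                                             sig_level = sig_level,
                                             ci_level = ci_level,
                                             separation_policy = separation_policy))
  }
  invisible(result)
}

# Write the six table artefacts plus manifest.json; on any write failure a
# FAILED marker is left so partial output is never mistaken for a run.
write_report_bundle <- function(result, out_dir, seed, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "FAILED")
  file.create(marker)
  tables <- c("descriptive_by_sex", "descriptive_by_ethnicity", "prevalence",
              "stepwise_trace", "final_model", "sensitivity_comparison")
  files <- character()
  for (t in tables) {
    f <- file.path(out_dir, paste0(t, ".csv"))
    utils::write.csv(result[[t]], f, row.names = FALSE, na = "")
    files[t] <- f
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    package = "dialdep",
    version = as.character(utils::packageVersion("dialdep")),
    seed = seed,
    config_hash = unname(tools::md5sum(tf)),
    n_tables = length(tables),
    tables = lapply(tables, function(t) {
      list(name = t, file = basename(files[[t]]),
           md5 = unname(tools::md5sum(files[[t]])))
    })
  )
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  unlink(marker)
  manifest
}
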