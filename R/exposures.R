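#' Declare how a participant field enters the model
#'
#' @param source Column name in the wide participant table.
#' @param type `"binary"` (0/1 indicator), `"categorical"`
#'   (reference-coded indicators) or `"continuous"`.
#' @param reference Reference level, required for categoricals. Table-style
#'   convention in this package: the largest group is the reference (for
#'   education that is completed schooling).
#' @param levels Optional explicit level order for categoricals; defaults to
#'   the registry order for known fields, otherwise the observed sorted
#'   levels.
#' @param name Display name; defaults to `source`.
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(source, type = c("binary", "categorical", "continuous"),
                           reference = NULL, levels = NULL, name = source) {
  type <- match.arg(type)
  if (type == "categorical" && is.null(reference)) {
    stop("categorical covariate '", source, "' needs a reference level",
         call. = FALSE)
  }
  structure(list(name = name, source = source, type = type,
                 reference = reference, levels = levels),
            class = "covariate_spec")
}

known_levels <- function(source) {
  switch(source,
         sex = sex_levels, ethnicity = ethnicity_levels,
         education = education_levels, occupation = occupation_levels,
         marital_status = marital_levels, smoking = smoking_levels,
         NULL)
}

#' Build a reference-coded design matrix and outcome vector
#'
#' Expands the covariate specs into numeric columns in spec order (a k-level
#' categorical contributes its k-1 non-reference indicators, named
#' `source.level`). The binary outcome is an ICD-10 diagnosis in the
#' moderate/severe band unless an explicit outcome vector is supplied. Rows
#' with any missing required covariate (or missing outcome) are flagged for
#' complete-case handling downstream; they are kept in the returned matrix so
#' callers can report exclusions.
#'
#' @param records Wide participant `data.frame`.
#' @param specs List of [covariate_spec()] objects.
#' @param outcome Binary outcome vector (logical or 0/1), or a diagnosis
#'   `data.frame`/factor from [classify_cohort()] (positive =
#'   `moderate_severe`). If `NULL` the records are classified with
#'   [rules_default()].
#' @return List with `X` (numeric `data.frame`), `y`, `complete` (logical
#'   complete-case index), `n_used` (`sum(complete)`) and `groups` (named
#'   list mapping each spec to its columns, used for whole-variable
#'   stepwise).
#' @export
build_design_matrix <- function(records, specs, outcome = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("empty cohort", call. = FALSE)
  }
  if (is.null(outcome)) outcome <- classify_cohort(records)
  if (is.data.frame(outcome)) outcome <- outcome$category
  if (is.factor(outcome) || is.character(outcome)) {
    outcome <- as.character(outcome) == "moderate_severe"
  }
  y <- as.integer(outcome)
  if (length(y) != nrow(records)) {
    stop("outcome length does not match the cohort", call. = FALSE)
  }

  cols <- list()
  groups <- list()
  for (sp in specs) {
    if (!sp$source %in% names(records)) {
      stop("unknown covariate source column: ", sp$source, call. = FALSE)
    }
    v <- records[[sp$source]]
    if (sp$type == "continuous") {
      cols[[sp$name]] <- as.numeric(v)
      groups[[sp$name]] <- sp$name
    } else if (sp$type == "binary") {
      if (is.logical(v)) v <- as.integer(v)
      if (!all(v %in% c(0, 1, NA))) {
        stop("binary covariate '", sp$source, "' has values outside {0,1}",
             call. = FALSE)
      }
      cols[[sp$name]] <- as.numeric(v)
      groups[[sp$name]] <- sp$name
    } else {
      lev <- sp$levels %||% known_levels(sp$source) %||% sort(unique(stats::na.omit(v)))
      v <- as.character(v)
      bad <- setdiff(unique(stats::na.omit(v)), lev)
      if (length(bad) > 0) {
        stop("unknown level(s) in '", sp$source, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      if (!sp$reference %in% lev) {
        stop("reference level '", sp$reference, "' not among levels of '",
             sp$source, "'", call. = FALSE)
      }
      g <- character()
      for (l in setdiff(lev, sp$reference)) {
        cn <- paste0(sp$name, ".", l)
        col <- as.numeric(v == l)
        col[is.na(v)] <- NA_real_
        cols[[cn]] <- col
        g <- c(g, cn)
      }
      groups[[sp$name]] <- g
    }
  }
  X <- as.data.frame(cols, check.names = FALSE)
  complete <- stats::complete.cases(X) & !is.na(y)
  list(X = X, y = y, complete = complete, n_used = sum(complete),
       groups = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Life-event and discrimination endorsement prevalence, stratified
#'
#' Per-item endorsement proportions with exact (Clopper-Pearson) binomial
#' confidence intervals, overall and optionally by stratum. Strata with no
#' observations are omitted with a warning.
#'
#' @param records Wide participant `data.frame`.
#' @param items Item columns to summarise; defaults to the 12 life events.
#' @param by Optional stratifying column (e.g. `"sex"`, `"ethnicity"`).
#' @param level Confidence level.
#' @return Tidy `data.frame`: `stratum`, `item`, `count`, `n`, `proportion`,
#'   `ci_low`, `ci_high`.
#' @export
event_prevalence <- function(records, items = paste0("le_", life_event_ids),
                             by = NULL, level = 0.95) {
  if (nrow(records) < 1) stop("empty cohort", call. = FALSE)
  strata <- if (is.null(by)) {
    list(overall = rep(TRUE, nrow(records)))
  } else {
    lev <- known_levels(by) %||% sort(unique(as.character(records[[by]])))
    out <- lapply(lev, function(l) !is.na(records[[by]]) & records[[by]] == l)
    names(out) <- lev
    empty <- vapply(out, sum, integer(1)) == 0
    if (any(empty)) {
      warning("omitting empty stratum(s): ",
              paste(names(out)[empty], collapse = ", "), call. = FALSE)
      out <- out[!empty]
    }
    out
  }
  rows <- list()
  for (s in names(strata)) {
    idx <- strata[[s]]
    for (it in items) {
      v <- records[[it]][idx]
      k <- sum(v == 1 | v == TRUE, na.rm = TRUE)
      n <- sum(!is.na(v))
      est <- prevalence(k, n, level = level)
      rows[[length(rows) + 1]] <- data.frame(
        stratum = s, item = it, count = k, n = n,
        proportion = est$proportion, ci_low = est$ci_low,
        ci_high = est$ci_high, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default covariate blocks for the adversity-and-comorbidity analysis
#'
#' Three blocks screened separately by backward stepwise regression before
#' the final model: demographics (age, sex, marital status, education,
#' occupation, alcohol, smoking), psychosocial exposures (12 threatening life
#' events and 5 discrimination items), and long-term conditions.
#'
#' @return Named list of lists of [covariate_spec()]s, one per block
#'   (`demographics`, `psychosocial`, `conditions`).
#' @export
block_specs <- function() {
  list(
    demographics = list(
      covariate_spec("age", "continuous"),
      covariate_spec("sex", "categorical", reference = "male"),
      covariate_spec("marital_status", "categorical", reference = "married"),
      covariate_spec("education", "categorical", reference = "school_complete"),
      covariate_spec("occupation", "categorical", reference = "retired"),
      covariate_spec("alcohol", "binary"),
      covariate_spec("smoking", "categorical", reference = "never")
    ),
    psychosocial = c(
      lapply(paste0("le_", life_event_ids), covariate_spec, type = "binary"),
      lapply(paste0("disc_", discrimination_ids), covariate_spec, type = "binary")
    ),
    conditions = lapply(paste0("cm_", comorbidity_ids), covariate_spec,
                        type = "binary")
  )
}
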