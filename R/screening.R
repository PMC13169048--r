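#' Score the 2-item Patient Health Questionnaire
#'
#' Total score is the sum of the two items (each 0-3); screening positivity
#' uses the conventional threshold of 3 or more. Missing items are an error:
#' no imputation or prorating is applied.
#'
#' @param items Numeric vector of length 2, each in 0-3.
#' @param threshold Positivity threshold (default 3).
#' @return List with `score` (0-6) and `positive`.
#' @export
score_phq2 <- function(items, threshold = 3L) {
  if (length(items) != 2) stop("PHQ-2 requires exactly 2 items", call. = FALSE)
  if (anyNA(items)) stop("missing PHQ-2 item; no imputation policy", call. = FALSE)
  if (any(items < 0 | items > 3 | items != round(items))) {
    stop("PHQ-2 items must be integers in 0-3", call. = FALSE)
  }
  s <- as.integer(sum(items))
  list(score = s, positive = s >= threshold)
}

#' Score the 17-item Hamilton Depression Rating Scale
#'
#' Per-item maxima follow the standard instrument: nine items scored 0-4 and
#' eight scored 0-2, for a maximum total of 52. The study threshold for
#' severe depressive symptoms is a total of 19 or more. Missing items are an
#' error for a single administration; cohort-level scoring excludes (never
#' prorates) incomplete administrations.
#'
#' @param items Numeric vector of length 17, item k within 0..`hamd_item_max[k]`.
#' @param threshold Positivity threshold (default 19).
#' @return List with `score` (0-52) and `positive`.
#' @export
score_hamd <- function(items, threshold = 19L) {
  if (length(items) != 17) stop("HAMD-17 requires exactly 17 items", call. = FALSE)
  if (anyNA(items)) stop("missing HAMD-17 item; incomplete administrations are excluded, not prorated",
                         call. = FALSE)
  if (any(items < 0 | items > hamd_item_max | items != round(items))) {
    bad <- which(items < 0 | items > hamd_item_max | items != round(items))
    stop("HAMD-17 item(s) out of range: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  s <- as.integer(sum(items))
  list(score = s, positive = s >= threshold)
}

#' Score both screening instruments for a cohort
#'
#' Rows with any missing item on an instrument get `NA` for that instrument's
#' score and positivity; the number excluded per instrument is recorded in
#' the `n_excluded` attribute and reported via `message()`.
#'
#' @param records Wide participant `data.frame` with columns `phq2_1`,
#'   `phq2_2`, `hamd_1` .. `hamd_17`.
#' @param quiet Suppress the exclusion message.
#' @return `data.frame` with `phq2_score`, `phq2_positive`, `hamd_score`,
#'   `hamd_positive`; attribute `n_excluded` is a named integer vector.
#' @export
screen_cohort <- function(records, quiet = FALSE) {
  phq <- as.matrix(records[, paste0("phq2_", 1:2), drop = FALSE])
  ham <- as.matrix(records[, paste0("hamd_", 1:17), drop = FALSE])
  if (any(phq < 0 | phq > 3, na.rm = TRUE)) {
    stop("PHQ-2 items out of range", call. = FALSE)
  }
  if (any(sweep(ham, 2, hamd_item_max, `-`) > 0, na.rm = TRUE) ||
      any(ham < 0, na.rm = TRUE)) {
    stop("HAMD-17 items out of range", call. = FALSE)
  }
  phq_ok <- stats::complete.cases(phq)
  ham_ok <- stats::complete.cases(ham)
  out <- data.frame(
    phq2_score = ifelse(phq_ok, rowSums(phq), NA_integer_),
    hamd_score = ifelse(ham_ok, rowSums(ham), NA_integer_)
  )
  out$phq2_positive <- out$phq2_score >= 3
  out$hamd_positive <- out$hamd_score >= 19
  out <- out[, c("phq2_score", "phq2_positive", "hamd_score", "hamd_positive")]
  n_excl <- c(phq2 = sum(!phq_ok), hamd = sum(!ham_ok))
  if (!quiet && any(n_excl > 0)) {
    message(sprintf("screen_cohort: excluded %d PHQ-2 and %d HAMD-17 incomplete administrations",
                    n_excl["phq2"], n_excl["hamd"]))
  }
  attr(out, "n_excluded") <- n_excl
  out
}

#' Concordance between screening positivity and the diagnostic reference
#'
#' Builds the 2x2 table of screen positivity against the ICD-10 reference
#' diagnosis and derives sensitivity, specificity, predictive values and
#' Cohen's kappa. Proportions with zero denominators are reported as `NA`,
#' never as 0.
#'
#' @param screen_positive Logical vector.
#' @param diagnosis Diagnosis categories: a factor/character vector with
#'   levels none/mild/moderate_severe, or the `data.frame` returned by
#'   [classify_cohort()].
#' @param positive_class Which diagnostic band counts as positive:
#'   `"moderate_severe"` (default) or `"any_depression"` (mild or worse).
#' @return An object of class `concordance_summary`: 2x2 table, the derived
#'   proportions, `kappa` and `n`.
#' @export
concordance <- function(screen_positive, diagnosis,
                        positive_class = c("moderate_severe", "any_depression")) {
  positive_class <- match.arg(positive_class)
  if (is.data.frame(diagnosis)) diagnosis <- diagnosis$category
  diagnosis <- as.character(diagnosis)
  if (length(screen_positive) != length(diagnosis)) {
    stop("screen and diagnosis vectors differ in length", call. = FALSE)
  }
  n <- length(diagnosis)
  if (n < 1) stop("empty cohort", call. = FALSE)
  dx_pos <- if (positive_class == "moderate_severe") {
    diagnosis == "moderate_severe"
  } else {
    diagnosis %in% c("mild", "moderate_severe")
  }
  keep <- !is.na(screen_positive) & !is.na(dx_pos)
  screen_positive <- screen_positive[keep]
  dx_pos <- dx_pos[keep]
  n <- sum(keep)

  tp <- sum(screen_positive & dx_pos)
  fp <- sum(screen_positive & !dx_pos)
  fn <- sum(!screen_positive & dx_pos)
  tn <- sum(!screen_positive & !dx_pos)
  tab <- matrix(c(tp, fn, fp, tn), nrow = 2,
                dimnames = list(screen = c("positive", "negative"),
                                diagnosis = c("positive", "negative")))

  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) NA_real_ else (po - pe) / (1 - pe)

  structure(
    list(
      two_by_two = tab,
      sensitivity = ratio(tp, tp + fn),
      specificity = ratio(tn, tn + fp),
      positive_predictive_value = ratio(tp, tp + fp),
      negative_predictive_value = ratio(tn, tn + fn),
      kappa = kappa,
      n = n,
      positive_class = positive_class
    ),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("Screen vs ICD-10 %s (n = %d)\n", x$positive_class, x$n))
  print(x$two_by_two)
  cat(sprintf("sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f  kappa %.3f\n",
              x$sensitivity, x$specificity, x$positive_predictive_value,
              x$negative_predictive_value, x$kappa))
  invisible(x)
}
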