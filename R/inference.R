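#' Exact binomial prevalence estimate
#'
#' Clopper-Pearson interval from beta quantiles: conservative coverage, and
#' the method that reproduces printed exact bounds for small-count
#' prevalences (Wilson does not).
#'
#' @param count Number of cases.
#' @param n Denominator (>= 1).
#' @param level Confidence level.
#' @return An object of class `prevalence_estimate`: `count`, `n`,
#'   `proportion`, `ci_low`, `ci_high`, `method`.
#' @examples
#' prevalence(24, 300)
#' @export
prevalence <- function(count, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (count < 0 || count > n) stop("count must be within 0..n", call. = FALSE)
  alpha <- 1 - level
  low <- if (count == 0) 0 else stats::qbeta(alpha / 2, count, n - count + 1)
  high <- if (count == n) 1 else stats::qbeta(1 - alpha / 2, count + 1, n - count)
  structure(
    list(count = as.integer(count), n = as.integer(n),
         proportion = count / n, ci_low = low, ci_high = high,
         level = level, method = "clopper_pearson"),
    class = "prevalence_estimate"
  )
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%d%% CI %.1f-%.1f, Clopper-Pearson)\n",
              x$count, x$n, 100 * x$proportion, round(100 * x$level),
              100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Contingency-table test with the small-cell switching rule
#'
#' Pearson chi-squared without continuity correction when every expected cell
#' count is at least `min_expected`, otherwise Fisher's exact test. The switch
#' is keyed on expected (not observed) counts, the conventional reading of
#' the small-cell rule; set `switch_on = "observed"` for the literal one.
#'
#' @param table Integer matrix, at least 2x2, non-negative, positive margins.
#' @param min_expected Switching threshold (default 5).
#' @param switch_on Key the rule on `"expected"` (default) or `"observed"`
#'   cell counts.
#' @return An object of class `contingency_result`: `table`, `method`
#'   (`chi_squared` or `fisher_exact`), `statistic` (chi-squared only),
#'   `p_value`, `min_expected_cell`.
#' @export
contingency_test <- function(table, min_expected = 5, switch_on = c("expected", "observed")) {
  switch_on <- match.arg(switch_on)
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("table must be at least 2x2", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  key <- if (switch_on == "expected") min(expected) else min(table)
  if (key < min_expected) {
    ft <- fisher_with_fallback(table)
    res <- list(method = "fisher_exact", statistic = NA_real_,
                p_value = ft$p.value, simulated = isTRUE(attr(ft, "simulated")))
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    res <- list(method = "chi_squared",
                statistic = unname(ct$statistic), p_value = ct$p.value)
  }
  structure(
    c(list(table = table), res,
      list(min_expected_cell = min(expected))),
    class = "contingency_result"
  )
}

# Exact test for 2x2 always. For larger tables full enumeration can be
# intractable (the network algorithm's time and workspace explode on dense
# margins), so tables beyond a small-total budget use a Monte Carlo exact
# test on a fixed internal RNG stream, keeping pipeline output deterministic.
fisher_with_fallback <- function(table) {
  if (nrow(table) == 2 && ncol(table) == 2) return(stats::fisher.test(table))
  mc <- function() {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    )
    set.seed(104729)
    ft <- stats::fisher.test(table, simulate.p.value = TRUE, B = 1e5)
    attr(ft, "simulated") <- TRUE
    ft
  }
  if (sum(table) > 100) return(mc())
  tryCatch(stats::fisher.test(table, workspace = 2e6),
           error = function(e) mc())
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("%s: p = %.4g (min expected cell %.2f)\n",
              x$method, x$p_value, x$min_expected_cell))
  invisible(x)
}

# Wald-based logistic fit summary shared by stepwise and the final model.
wald_summary <- function(fit, level = 0.95) {
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    odds_ratio = exp(sm[, "Estimate"]),
    ci_low = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
    ci_high = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
    p_value = sm[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Fit logistic y ~ X (X a numeric data.frame) on complete cases; detect
# separation-like instability from exploding coefficients/SEs.
fit_logistic <- function(X, y, level = 0.95) {
  dat <- cbind(data.frame(.y = y), X)
  names(dat) <- c(".y", names(X))
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial())
  )
  terms <- wald_summary(fit, level)
  separated <- any(abs(terms$estimate) > 15 | terms$std_error > 100)
  list(fit = fit, terms = terms, converged = fit$converged,
       separated = separated)
}

#' Backward stepwise logistic regression at a retention threshold
#'
#' Iteratively fits the logistic model and removes the variable with the
#' largest Wald p-value at or above the threshold, refitting until every
#' remaining variable is below it. Multi-level categoricals enter and leave
#' as whole variables; a variable's p-value for removal is the smallest Wald
#' p among its indicator columns, so a categorical with any significant level
#' is kept. Ties on the removal p-value are broken deterministically by
#' dropping the variable latest in the declared covariate order.
#'
#' @param X Numeric design `data.frame` (e.g. `build_design_matrix()$X`).
#' @param y Binary outcome (0/1), same length as `nrow(X)`.
#' @param threshold Retention threshold on the Wald p-value (default 0.1).
#' @param groups Named list mapping variables to their columns in `X`;
#'   defaults to one singleton group per column.
#' @param complete Optional logical complete-case index; defaults to rows
#'   complete across `X` and `y`.
#' @param separation_policy What to do when a fit looks separated:
#'   `"error"` (default, fail loudly), `"flag"` (continue, flag the result)
#'   or `"firth"` (refit with Jeffreys-penalized likelihood).
#' @return An object of class `stepwise_trace`: `removal_sequence`
#'   (`data.frame` of variable, p_at_removal, step), `retained` (variables
#'   with their minimum final p), `final` (the terminal
#'   `logistic_model_result`, `NULL` if everything was removed), `n_used`.
#' @export
backward_stepwise <- function(X, y, threshold = 0.1, groups = NULL,
                              complete = NULL,
                              separation_policy = c("error", "flag", "firth")) {
  separation_policy <- match.arg(separation_policy)
  if (is.null(groups)) groups <- stats::setNames(as.list(names(X)), names(X))
  if (is.null(complete)) complete <- stats::complete.cases(X) & !is.na(y)
  Xc <- X[complete, , drop = FALSE]
  yc <- y[complete]
  if (length(unique(yc)) < 2) {
    stop("outcome has a single class on complete cases", call. = FALSE)
  }
  if (length(groups) < 1) stop("no candidate variables", call. = FALSE)

  vars <- names(groups)          # declared order, used for tie-breaking
  active <- vars
  removal <- list()
  step <- 0L
  final <- NULL
  repeat {
    if (length(active) == 0) break
    cols <- unlist(groups[active], use.names = FALSE)
    res <- fit_model_checked(Xc[, cols, drop = FALSE], yc,
                             separation_policy)
    var_p <- vapply(active, function(v) {
      p <- res$terms$p_value[res$terms$term %in% groups[[v]]]
      if (length(p) == 0) 1 else min(p)   # aliased/constant columns: removable
    }, numeric(1))
    removable <- var_p >= threshold
    if (!any(removable)) {
      final <- res
      break
    }
    worst <- max(var_p[removable])
    # ties: drop the variable latest in declared order
    cand <- active[removable & abs(var_p - worst) < 1e-12]
    drop_var <- cand[which.max(match(cand, vars))]
    step <- step + 1L
    removal[[step]] <- data.frame(variable = drop_var,
                                  p_at_removal = var_p[[drop_var]],
                                  step = step, stringsAsFactors = FALSE)
    active <- setdiff(active, drop_var)
  }

  retained_p <- if (!is.null(final)) {
    stats::setNames(vapply(active, function(v) {
      p <- final$terms$p_value[final$terms$term %in% groups[[v]]]
      if (length(p) == 0) 1 else min(p)
    }, numeric(1)), active)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(
    list(
      removal_sequence = if (step > 0) do.call(rbind, removal) else
        data.frame(variable = character(), p_at_removal = numeric(),
                   step = integer()),
      retained = retained_p,
      final = final,
      threshold = threshold,
      n_used = length(yc)
    ),
    class = "stepwise_trace"
  )
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat(sprintf("Backward stepwise (retain at p < %g), n = %d\n",
              x$threshold, x$n_used))
  if (nrow(x$removal_sequence) > 0) {
    for (i in seq_len(nrow(x$removal_sequence))) {
      cat(sprintf("  step %d: removed %s (p = %.3f)\n",
                  x$removal_sequence$step[i], x$removal_sequence$variable[i],
                  x$removal_sequence$p_at_removal[i]))
    }
  }
  cat("  retained:", if (length(x$retained) > 0)
    paste(sprintf("%s (p=%.3g)", names(x$retained), x$retained),
          collapse = ", ") else "(none)", "\n")
  invisible(x)
}

fit_model_checked <- function(X, y, separation_policy) {
  res <- fit_logistic(X, y)
  if (res$separated) {
    if (separation_policy == "error") {
      stop("apparent complete separation; refusing to report unstable odds ratios ",
           "(set separation_policy = 'firth' or 'flag' to override)",
           call. = FALSE)
    }
    if (separation_policy == "firth") {
      fl <- firth_logistic(cbind(`(Intercept)` = 1, as.matrix(X)), y)
      res$terms <- fl$terms
      res$converged <- fl$converged
      res$penalized <- TRUE
    }
  }
  res
}

#' Fit the final multivariable logistic model
#'
#' Maximum-likelihood logistic regression of the binary diagnosis on the
#' supplied design columns, with Wald confidence intervals, the model
#' likelihood-ratio chi-squared against the null, McFadden's pseudo R-squared
#' and a significance flag at the reporting level.
#'
#' @inheritParams backward_stepwise
#' @param level Confidence level for Wald intervals.
#' @param sig_level Flagging threshold for reported significance (default
#'   0.05).
#' @return An object of class `logistic_model_result`: `terms` (term,
#'   estimate, odds_ratio, Wald CI, p-value, `significant`), `n_used`,
#'   `model_chi2`, `df`, `p_model`, `pseudo_r2`, `converged`, `separated`.
#' @export
fit_final_model <- function(X, y, complete = NULL, level = 0.95,
                            sig_level = 0.05,
                            separation_policy = c("error", "flag", "firth")) {
  separation_policy <- match.arg(separation_policy)
  if (is.null(complete)) complete <- stats::complete.cases(X) & !is.na(y)
  Xc <- X[complete, , drop = FALSE]
  yc <- y[complete]
  res <- fit_model_checked(Xc, yc, separation_policy)
  fit <- res$fit
  terms <- res$terms
  terms$significant <- terms$p_value <= sig_level
  chi2 <- unname(fit$null.deviance - fit$deviance)
  df <- unname(fit$df.null - fit$df.residual)
  structure(
    list(
      terms = terms,
      n_used = length(yc),
      model_chi2 = chi2,
      df = df,
      p_model = stats::pchisq(chi2, df, lower.tail = FALSE),
      pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
      converged = res$converged,
      separated = res$separated,
      penalized = isTRUE(res$penalized)
    ),
    class = "logistic_model_result"
  )
}

#' @export
print.logistic_model_result <- function(x, digits = 2, ...) {
  cat(sprintf("Logistic model: N = %d, X2 (d.f. = %d) = %.2f, R2 = %.2f, p %s\n",
              x$n_used, x$df, x$model_chi2, x$pseudo_r2,
              format.pval(x$p_model, eps = 1e-4)))
  tab <- x$terms
  tab$odds_ratio <- round(tab$odds_ratio, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab[, c("term", "odds_ratio", "ci_low", "ci_high", "p_value",
                "significant")], row.names = FALSE)
  invisible(x)
}

#' Jeffreys-penalized (Firth-type) logistic regression
#'
#' Newton-Raphson maximisation of the Jeffreys-penalized likelihood, used as
#' the fallback when maximum likelihood shows complete or quasi-complete
#' separation. The score is adjusted by the hat-diagonal term
#' `h_i (1/2 - p_i)`, which keeps estimates finite under separation.
#'
#' @param X Numeric model matrix including an intercept column.
#' @param y Binary outcome.
#' @param maxit,tol Iteration controls.
#' @return List with `terms` (Wald summary on the penalized fit),
#'   `coefficients` and `converged`.
#' @export
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XtW <- t(X * w)
    info <- XtW %*% X
    inv <- solve(info)
    h <- rowSums((X %*% inv) * X) * w
    score <- drop(t(X) %*% (y - p + h * (0.5 - p)))
    delta <- drop(inv %*% score)
    # dampen oversized steps for stability near separation
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    beta <- beta + delta
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
  }
  se <- sqrt(diag(inv))
  z <- beta / se
  terms <- data.frame(
    term = colnames(X) %||% paste0("b", seq_along(beta)),
    estimate = beta, std_error = se,
    odds_ratio = exp(beta),
    ci_low = exp(beta - stats::qnorm(0.975) * se),
    ci_high = exp(beta + stats::qnorm(0.975) * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(terms = terms, coefficients = stats::setNames(beta, colnames(X)),
       converged = converged)
}
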