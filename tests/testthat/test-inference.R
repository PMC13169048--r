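test_that("exact binomial interval hits the boundary cases and the 24/300 band", {
  p0 <- prevalence(0, 10)
  expect_equal(p0$ci_low, 0)
  expect_equal(p0$proportion, 0)
  pn <- prevalence(10, 10)
  expect_equal(pn$ci_high, 1)
  est <- prevalence(24, 300)
  expect_equal(est$proportion, 0.08)
  expect_true(est$ci_low <= est$proportion && est$proportion <= est$ci_high)
  expect_error(prevalence(5, 0), ">= 1")
  expect_error(prevalence(11, 10), "within 0..n")
})

test_that("exact intervals are conservative: coverage >= 0.95 at p = 0.08, n = 300", {
  set.seed(41)
  draws <- rbinom(2000, 300, 0.08)
  covered <- vapply(draws, function(k) {
    est <- prevalence(k, 300)
    est$ci_low <= 0.08 && 0.08 <= est$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("the switching rule keys on expected cells and picks the right test", {
  r1 <- contingency_test(matrix(c(1, 1, 1, 1), 2))
  expect_equal(r1$method, "fisher_exact")
  expect_equal(r1$p_value, 1)

  r2 <- contingency_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r2$method, "chi_squared")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)

  # uneven margins: all observed >= 5 but an expected cell below 5
  tab <- matrix(c(5, 45, 5, 5), 2)
  expect_lt(min(outer(rowSums(tab), colSums(tab)) / sum(tab)), 5)
  expect_equal(contingency_test(tab)$method, "fisher_exact")
  expect_equal(contingency_test(tab, switch_on = "observed")$method,
               "chi_squared")

  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
  expect_error(contingency_test(matrix(c(1, -1, 3, 4), 2)), "non-negative")
})

test_that("chi-squared branch is Pearson without continuity correction", {
  tab <- matrix(c(20, 30, 40, 10), 2)
  r <- contingency_test(tab)
  expect_equal(r$method, "chi_squared")
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
})

test_that("Fisher p-values match hypergeometric enumeration on random small tables", {
  set.seed(42)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, 3) + c(1, 0, 0, 1), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    if (min(outer(rowSums(tab), colSums(tab)) / sum(tab)) >= 5) next
    r <- contingency_test(tab)
    expect_equal(r$method, "fisher_exact")
    expect_equal(r$p_value, oracle_fisher_2x2(tab), tolerance = 1e-10)
  }
})

test_that("stepwise keeps a strong simulated predictor and drops a null one", {
  set.seed(43)
  n <- 2000
  x_strong <- rbinom(n, 1, 0.5)
  x_null <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-2.2 + log(5) * x_strong))
  X <- data.frame(strong = x_strong, null = x_null)

  tr <- backward_stepwise(X, y, threshold = 0.1)
  expect_true("strong" %in% names(tr$retained))
  expect_lt(tr$retained[["strong"]], 1e-6)
  expect_true(all(tr$removal_sequence$p_at_removal >= 0.1))

  # a lone null predictor is removed, leaving nothing retained
  tr0 <- backward_stepwise(data.frame(null = x_null), y, threshold = 0.1)
  expect_equal(length(tr0$retained), 0)
  expect_equal(tr0$removal_sequence$variable, "null")
})

test_that("removal order matches exhaustive refits on a two-variable problem", {
  set.seed(44)
  n <- 3000
  x_strong <- rbinom(n, 1, 0.5)
  x_null <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-2 + log(4) * x_strong))
  X <- data.frame(null = x_null, strong = x_strong)
  tr <- backward_stepwise(X, y)
  # oracle: fit the full model once by hand, confirm the larger p is the null's
  full <- glm(y ~ null + strong, data = cbind(X, y = y), family = binomial())
  p <- summary(full)$coefficients[c("null", "strong"), "Pr(>|z|)"]
  expect_gt(p[["null"]], p[["strong"]])
  expect_equal(tr$removal_sequence$variable, "null")
  expect_equal(names(tr$retained), "strong")
})

test_that("stepwise is deterministic and treats categoricals as whole variables", {
  coh <- generate_cohort(preset_dialysis(n = 3000, seed = 45))
  dm <- build_design_matrix(coh$records, block_specs()$demographics)
  tr1 <- backward_stepwise(dm$X, dm$y, groups = dm$groups, complete = dm$complete)
  tr2 <- backward_stepwise(dm$X, dm$y, groups = dm$groups, complete = dm$complete)
  expect_identical(tr1$removal_sequence, tr2$removal_sequence)
  expect_identical(tr1$retained, tr2$retained)
  # removals happen at the variable level, never a bare indicator column
  expect_true(all(tr1$removal_sequence$variable %in% names(dm$groups)))
  # education is driven by a strong simulated protective effect: retained
  expect_true("education" %in% names(tr1$retained))
})

test_that("null-model intercept equals the closed-form log-odds of the prevalence", {
  set.seed(46)
  y <- rbinom(4000, 1, 0.08)
  X0 <- data.frame(row.names = seq_along(y))  # intercept-only design
  fm <- fit_final_model(X0, y, complete = rep(TRUE, 4000))
  expect_equal(fm$terms$estimate[fm$terms$term == "(Intercept)"],
               log(mean(y) / (1 - mean(y))), tolerance = 1e-6)
  expect_equal(fm$df, 0)
})

test_that("final model reports Wald intervals, fit statistics and term count", {
  coh <- generate_cohort(preset_dialysis(n = 5000, seed = 47))
  dm <- build_design_matrix(
    coh$records,
    c(list(covariate_spec("age", "continuous"),
           covariate_spec("sex", "categorical", reference = "male")),
      lapply(c("cm_diabetes_t2", "le_financial_crisis"), covariate_spec,
             type = "binary")))
  fm <- fit_final_model(dm$X, dm$y, complete = dm$complete)
  expect_equal(fm$df, ncol(dm$X))
  expect_equal(fm$n_used, sum(dm$complete))
  expect_true(all(fm$terms$ci_low <= fm$terms$odds_ratio &
                    fm$terms$odds_ratio <= fm$terms$ci_high))
  expect_equal(fm$terms$odds_ratio, exp(fm$terms$estimate))
  expect_true(fm$converged)
  expect_gt(fm$model_chi2, 0)
  expect_true(fm$pseudo_r2 > 0 && fm$pseudo_r2 < 1)
  # refitting on pre-filtered complete cases changes nothing
  fm2 <- fit_final_model(dm$X[dm$complete, , drop = FALSE], dm$y[dm$complete])
  expect_equal(fm2$n_used, fm$n_used)
  expect_equal(fm2$terms$estimate, fm$terms$estimate)
})

test_that("complete separation fails loudly by default and Firth stabilises it", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x  # perfectly separated
  X <- data.frame(x = x)
  expect_error(fit_final_model(X, y), "separation")
  flagged <- fit_final_model(X, y, separation_policy = "flag")
  expect_true(flagged$separated)
  firth <- fit_final_model(X, y, separation_policy = "firth")
  expect_true(all(is.finite(firth$terms$estimate)))
  expect_lt(max(abs(firth$terms$estimate)), 10)
})

test_that("Firth penalization agrees with maximum likelihood on well-behaved data", {
  set.seed(48)
  n <- 20000
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x))
  ml <- glm(y ~ x, family = binomial())
  fl <- firth_logistic(cbind(1, x), y)
  expect_true(fl$converged)
  expect_equal(unname(fl$coefficients), unname(coef(ml)), tolerance = 1e-2)
})
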