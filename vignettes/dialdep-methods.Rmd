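---
title: "Methods: depression classification and adversity modelling in dialysis cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depression classification and adversity modelling in dialysis cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialdep)
```

## The diagnostic model

`dialdep` operationalises the ICD-10 depressive-episode criteria (F32) as a
count-based rule over the CIS-R depression section, in the tradition of the
national psychiatric morbidity surveys that map structured-interview items
to diagnoses algorithmically. A profile holds binary endorsements of three
*core* symptoms — depressed mood, loss of interest, fatigue — and six
*additional* symptoms (concentration, low self-esteem, guilt,
pessimism/suicidality, sleep disturbance, agitation/retardation), an episode
duration in weeks, and a set of somatic-syndrome criteria.

The default `rule_table()` requires, for any episode, duration ≥ 2 weeks,
≥ 2 core symptoms and ≥ 4 total symptoms; 4–5 total grade *mild*, 6–7
*moderate*, and ≥ 8 with all three core symptoms *severe*. Moderate and
severe are collapsed into a single `moderate_severe` reporting band (a
`severe_subflag` is carried for traceability but never reported separately),
because at realistic cohort sizes the severe stratum is too thin to analyse.
All of these constants are data, not code: a different operationalisation is
a different YAML file, not a code change.

Three CIS-R items — appetite change, weight change and functional
impairment — are *representable but unset* under the dialysis administration
protocol, because dialysis itself disturbs appetite, weight and daily
functioning in nearly everyone, which destroys those items' diagnostic
value. Under the default rules these items are ignored entirely: a
classification can never depend on their stored values, set or not (this
"exclusion soundness" is a tested invariant). The shipped *sensitivity* rule
table instead counts all three as endorsed for every participant. This
brackets the classification from above: every participant's total symptom
count rises by exactly three, so the moderate/severe count can only grow.
The imputation includes the impairment item as symptom-contributing (one of
the three added counts); treating impairment as non-contributing would only
shrink the shift by one symptom and is achievable by editing
`excluded_items` in the YAML.

With appetite and weight removed from the somatic-criterion set, five
criteria remain (diurnal variation, early waking, loss of reactivity, libido
loss, psychomotor change) and the somatic-syndrome qualifier requires ≥ 3 of
them (configurable; the full eight-item criterion uses ≥ 4 of 8). The
qualifier is only defined for diagnosed episodes and is reported `FALSE`
otherwise.

Duration is modelled as a non-negative number of weeks. Interview routing
(skip patterns, question re-ordering to shorten administration) is treated
as a data-collection concern outside the scoring contract: the engine sees
only the resulting endorsements.

## Screening instruments

PHQ-2 items are 0–3 and positivity is total ≥ 3; HAMD-17 uses the standard
per-item maxima (nine items 0–4, eight 0–2; maximum 52) and positivity at
total ≥ 19. Missing items are never prorated: a single administration with a
missing item is an error, and cohort scoring excludes that instrument for
that participant with a logged count. Prorating rules vary between studies
and silently reweight items; exclusion is conservative and visible.

Concordance between a screen and the diagnostic reference is summarised by
the 2×2 table, sensitivity, specificity, predictive values and Cohen's κ.
Zero-denominator proportions are reported as `NA`, not 0 — an all-positive
screen has *undefined* negative predictive value, not a perfect one.

## Statistical procedures

**Prevalence.** Exact Clopper–Pearson intervals from beta quantiles. The
choice is deliberate: for small-count prevalences the exact interval is the
one whose printed bounds arithmetic on the counts reproduces, and its
conservatism (coverage ≥ nominal) is verified as a simulation property in
the test suite (2,000 binomial draws at p = 0.08, n = 300).

**Contingency tests.** Pearson χ² *without* continuity correction when
every expected cell count is ≥ 5, otherwise Fisher's exact test. The switch
is keyed on expected counts — the conventional reading of the small-cell
rule — with `switch_on = "observed"` available for the literal one. For 2×2
tables the exact test is always full enumeration; for larger tables with
totals above 100 (where the exact network algorithm's time and memory
explode) a Monte Carlo exact test on a fixed internal RNG stream is used, so
pipeline output remains deterministic.

**Stepwise screening.** Covariates are screened in three blocks —
demographics, psychosocial exposures (12 threatening life events + 5
discrimination items), long-term conditions — by backward elimination:
repeatedly fit the logistic model, remove the variable with the largest
Wald p ≥ 0.1, refit, stop when everything retained is below the threshold.
Wald z-tests (not likelihood-ratio tests) are used for removal because the
reporting convention is OR + Wald CI + p triplets, and mixing criteria makes
retained sets inconsistent with the printed p-values. Multi-level
categoricals move as whole variables, using the *minimum* indicator p as the
variable's p — a variable with any significant level is never removed. Ties
are broken by dropping the variable latest in the declared covariate order,
making the trace deterministic. Indicators that become constant (aliased) on
the analysis rows are treated as removable at p = 1.

**Final model.** The union of block-retained variables plus age and sex
(always included, as residual-confounding guards) is refit by maximum
likelihood on complete cases. Reported: per-term log-odds, OR, Wald 95% CI,
p-value with a p ≤ 0.05 flag, the model likelihood-ratio χ² against the
null, its degrees of freedom, and McFadden's pseudo-R²
(1 − deviance/null deviance).

**Missing data.** Complete-case (listwise) deletion per fitted model, with
the complete-case index and `n_used` always reported; the pipeline logs the
n at every filtering step because the gap between recruited and analysed n
is itself analytically meaningful. No imputation of covariates is offered.

**Separation.** Logistic fits are checked for separation-like instability
(|coefficient| > 15 or SE > 100 on the indicator scale). The default policy
is to fail loudly rather than report unstable odds ratios; `"flag"`
continues with a flag (the pipeline's default, since descriptive re-runs
should not abort on a thin stratum), and `"firth"` refits with
Jeffreys-penalized likelihood (Newton–Raphson with the hat-diagonal score
adjustment, step-halving above step size 5), which keeps estimates finite
under separation and agrees with maximum likelihood on well-behaved data.

## The synthetic cohort generator

Patient-level data of this kind are rarely depositable, so the generator is
a first-class, tested module, not a fixture. Its defaults describe a
300-person urban, ethnically diverse haemodialysis cohort:

- **Demographics**: sex 56/44 male/female; ethnicity 30% White British, 35%
  South Asian, 25% Black, 10% other; education 10% none, 20% incomplete
  schooling, 40% completed schooling (the reference and largest group), 22%
  university/apprenticeship, 8% other; age normal(60, 14) truncated to
  18–95; mostly retired or not in work, as expected on maintenance dialysis.
- **Comorbidity**: high hypertension (75%, 85% in the Black group), type 2
  diabetes 30% overall with ethnic structure (South Asian 45%, White British
  30%, Black 18%), cardiovascular disease 35%, obesity 25%, cancer 12% (18%
  White British), COPD 8%, autoimmune 10% (5% White British). Couplings
  beyond these explicit ethnicity overrides are *not* modelled: the
  generator is transparent about using independent marginals rather than
  inventing an unpublishable joint distribution.
- **Adversity**: 12-item threatening-life-event probabilities dominated by
  illness events (own serious illness 40%, relative's 25%), bereavements
  (parent/child/spouse 12%, friend/relative 18%), financial crisis 15%;
  5-item discrimination battery with higher racial-insult and unfair-
  treatment rates in minority groups.
- **Outcome**: moderate/severe depression is Bernoulli with
  logit p = intercept + log(5.32)·diabetes₂ + log(3.62)·bereavement +
  log(3.51)·financial crisis + log(0.18)·university. The intercept is not a
  guess: the effect indicators' joint distribution is enumerated exactly
  (ethnicity mixtures folded into the diabetes marginal) and the intercept
  root-found so the expected marginal prevalence is exactly 8%. Bisection on
  a closed enumeration was chosen over Monte Carlo because the covariate
  mixture makes the marginal non-analytic but still exactly summable.
  Non-cases become mild cases with probability 53/276, matching the
  mild-to-non-case ratio such a cohort reports.
- **Instruments**: given the category, a latent severity z is drawn
  (N(0,1) for none, N(1.6, 0.7) mild, N(2.8, 0.7) moderate/severe). CIS-R
  profiles are built by drawing a category-consistent core/total symptom
  target and sampling which items are endorsed, so `classify()` recovers the
  label *exactly* at the default `symptom_noise = 0` (a construction
  invariant, tested); a positive noise rate flips items for
  misclassification studies. HAMD items are binomial with success
  probability plogis(0.9·(z − 1.75)) (per-item maxima respected) and PHQ-2
  items binomial(3, plogis(z − 1.8)); these midpoints were calibrated once
  so that overall screening positivity lands near 24% (PHQ-2) and 30%
  (HAMD) against the 8% diagnosed prevalence — i.e. the screens over-call
  by the factor such surveys report — and were not revisited afterwards.
  Somatic criteria are binomial(5, p) with p = 0.15/0.30/0.55 by category.
- **Missingness**: small MCAR rates on education, occupation, marital
  status, smoking and alcohol (2–3%), so roughly a tenth of records drop
  out of complete-case regression — the recruited-vs-analysed gap the
  pipeline is required to log.

What the generator does *not* emulate: recruitment and refusal processes,
interviewer judgement in symptom endorsement, item-level ordinal CIS-R
scores (endorsements are binary), correlation between adversity items, or
instrument behaviour differing across ethnic groups. Passing tests on this
cohort therefore show the *pipeline* is correct under its stated model, not
that the model captures every feature of real dialysis populations.

## Problem sizes and numerical choices

The test suite runs the classifier-versus-oracle check exhaustively (2⁹
endorsement patterns × 4 durations × 6 somatic counts = 12,288 cases),
Fisher's test against full hypergeometric enumeration on every 2×2 table
with total ≤ 40, coverage of the exact interval over 2,000 simulated
binomials, stepwise behaviour over 200 replicates of n = 2,000, and
parameter recovery by refitting the final model on a single n = 50,000
preset cohort, where each recovered OR is required within 10% of its
configured value — a width chosen from the Wald standard errors that design
implies (≈ 0.03–0.08 on the log scale for these effects). The rarest
configuration, university education (22% exposure, ~2% event rate within
it), has the widest sampling error, close to the 10% band itself; a failure
there on an unlucky seed is sampling noise, not bias, and the estimate is
unbiased by construction.

One behavioural note on backward elimination at threshold 0.1: a truly null
predictor has an approximately uniform p-value, so it survives screening
with probability ≈ 0.1 by design. Joint "keep the real effect, drop the
null" success over replicates therefore concentrates near 90%, which is a
property of the p < 0.1 retention rule itself, not of the implementation;
the test suite measures exactly this rate.

Ties in stepwise removal are broken by declared covariate order (latest
dropped first); the Firth fallback uses score tolerance 1e-8 with damped
Newton steps; Clopper–Pearson bounds use `qbeta` directly with the 0 and 1
boundary cases handled explicitly; and every generator draw is governed by
a single integer seed, so a config is a complete description of a dataset.

## Known limitations

- The rule constants are the standard survey operationalisation of ICD-10
  F32; studies using CIS-R ordinal item scores rather than binary
  endorsements need a different rule table (and profile type) than shipped.
- The sensitivity mode imputes all three excluded items for *every*
  participant; on synthetic cohorts this roughly triples the moderate/severe
  count, an upper bound rather than an estimate of the true undercount.
- Backward stepwise selection inherits all the usual caveats (overfitting,
  order dependence under collinearity); it is provided because it is the
  screening procedure this analysis tradition uses, not as a recommendation.
- The generator's independence assumptions make it unsuitable for studying
  confounding structure beyond the configured couplings.
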