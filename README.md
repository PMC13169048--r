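# dialdep

Depression classification and psychosocial risk modelling for haemodialysis
cohorts.

## The problem

Depression is common in end-stage kidney disease, but much of what screening
instruments count as "depression" in dialysis patients overlaps with the
disease and its treatment: poor appetite, weight change and impaired daily
functioning are near-universal on dialysis whether or not a depressive
episode is present. Cross-sectional psychiatric surveys in this population
therefore need (i) a structured-interview diagnosis whose algorithm can
*exclude* those confounded items, (ii) a way to quantify how much routine
screening tools (PHQ-2, HAMD-17) over-call relative to that diagnosis, and
(iii) regression machinery linking the diagnosis to psychosocial adversity
(threatening life events, discrimination) and comorbidity.

`dialdep` implements that full analysis path for researchers running or
re-analysing such surveys:

- **Rule engine** — codes CIS-R depression-section endorsements into ICD-10
  depressive-episode categories (none / mild / moderate–severe, with a
  somatic-syndrome qualifier). All thresholds live in a declarative
  `rule_table()`: an episode requires duration ≥ 2 weeks and ≥ 2 of the 3
  core symptoms (depressed mood, loss of interest, fatigue); 4–5 total
  symptoms grade mild, 6–7 moderate, ≥ 8 with all core symptoms severe.
  The appetite, weight and impairment items are excluded under the dialysis
  protocol and ignored; a *sensitivity* rule table instead imputes all three
  as present for every participant, bounding how much the exclusion can
  undercount.
- **Screening** — PHQ-2 (positive at total ≥ 3) and HAMD-17 (positive at
  total ≥ 19, standard per-item maxima, no prorating of missing items), plus
  screen-versus-diagnosis concordance (2×2 table, sensitivity/specificity/
  predictive values, Cohen's κ).
- **Inference** — exact Clopper–Pearson binomial intervals for prevalence;
  contingency tests with the small-cell switching rule (Pearson χ² without
  continuity correction when all expected cells ≥ 5, otherwise Fisher's
  exact test); per-block backward stepwise logistic regression that removes
  the least significant variable (whole categorical variables at a time,
  minimum-indicator-p rule) until everything retained has Wald p < 0.1; and
  a final model with Wald 95% CIs, the model χ², McFadden pseudo-R² and
  p ≤ 0.05 flags. Complete separation fails loudly by default, with a
  Firth-type penalized fallback.
- **Synthetic cohort generator** — because patient-level data of this kind
  are rarely shareable, `preset_dialysis()` defines a 300-person urban,
  ethnically diverse haemodialysis cohort: marginal prevalence of
  moderate/severe depression 8% (intercept solved exactly by enumeration),
  depression odds driven by type 2 diabetes (OR 5.32), death of a spouse,
  child or parent (OR 3.62), major financial crisis (OR 3.51) and
  university-level education (OR 0.18 vs completed schooling). A latent
  severity process generates CIS-R profiles that the rule engine recovers
  exactly, and PHQ-2/HAMD-17 items calibrated so screening positivity
  (~24% / ~30%) exceeds the diagnosed 8% — the over-estimation phenomenon
  as a testable property.
- **Pipeline** — `run_full_pipeline()` validates a participant CSV and emits
  descriptive tables by sex and ethnicity, prevalence estimates per
  depression definition, stepwise traces, the final model and a
  default-versus-sensitivity comparison, with a JSON manifest (seed, config
  hash, per-table md5) for reproducibility. A thin CLI wrapper lives at
  `inst/cli/dialdep.R`.

## Worked example

```r
library(dialdep)

coh <- generate_cohort(preset_dialysis(seed = 7))   # n = 300
dx  <- classify_cohort(coh$records)
table(dx$category)
#>            none            mild moderate_severe
#>             215              58              27

prevalence(sum(dx$category == "moderate_severe"), nrow(coh$records))
#> 27/300 = 9.0% (95% CI 6.0-12.8, Clopper-Pearson)

scr <- screen_cohort(coh$records, quiet = TRUE)
concordance(scr$phq2_positive, dx)
#> Screen vs ICD-10 moderate_severe (n = 300)
#>           diagnosis
#> screen     positive negative
#>   positive       26       58
#>   negative        1      215
#> sensitivity 0.963  specificity 0.788  PPV 0.310  NPV 0.995  kappa 0.385

sum(classify_cohort(coh$records, rules_sensitivity())$category == "moderate_severe")
#> [1] 93   # imputing appetite/weight/impairment as present: 27 -> 93 cases

res <- run_full_pipeline(coh$records, out_dir = NULL)
res$final_fit
#> Logistic model: N = 289, X2 (d.f. = 8) = 39.16, R2 = 0.22, p < 1e-04
#>                          term odds_ratio ci_low ci_high p_value significant
#>                   (Intercept)       0.04   0.00    0.35 0.00410        TRUE
#>                       alcohol       2.03   0.84    4.90 0.11000       FALSE
#>                  smoking.past       3.31   1.23    8.92 0.01800        TRUE
#>               smoking.current       1.38   0.38    5.05 0.62000       FALSE
#>  le_death_parent_child_spouse       3.47   1.17   10.30 0.02500        TRUE
#>           le_financial_crisis       6.46   2.40   17.34 0.00021        TRUE
#>                cm_diabetes_t2       7.60   2.85   20.23 0.00005        TRUE
#>                           age       0.98   0.94    1.01 0.15000       FALSE
#>                    sex.female       1.10   0.46    2.66 0.83000       FALSE
```

At n = 300 the prevalence estimate (9.0%, CI 6.0–12.8) sits within binomial
noise of the configured 8%; the three adversity/comorbidity effects that
were configured in the generator come out with elevated odds ratios, and the
sensitivity re-classification roughly triples the moderate/severe count —
the direction and rough magnitude expected when three additional symptoms
are imputed for everyone. Sampling noise at this size also produces some
spurious retained covariates (here smoking/alcohol), which is exactly why
the recovery checks in the test suite run at n = 50,000.

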