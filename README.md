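# delirisk

Rule-based delirium risk prediction and prevention support for long-term
care facilities (LCFs), as an R package.

Delirium in LCF residents is frequent (incidence around 8%) but rarely
recognised early enough to prevent. delirisk implements a transparent
clinical-decision-support core for that setting, aimed at nurses,
informaticians and methodologists who want an inspectable alternative to
black-box risk scores:

* **Knowledge model** — IF–THEN rules over a 24-factor binary/categorical
  risk schema, with class-association support and confidence over a
  training cohort and a JSON rule-base store
  (support(r) = 100·#{matches ∧ decision}/N;
  confidence(r) = 100·#{matches ∧ decision}/#{matches}).
* **Rule induction** — the LEM2 rough-set local-covering algorithm:
  certain (lower-approximation) rules that are consistent, minimal and
  jointly complete, induced deterministically.
* **Inference engine** — matching degree (% of a rule's conditions a
  record satisfies), best-rule selection with a support × confidence
  tie-break, risk tertiles on rule support (low < 1.73%,
  medium ∈ [1.73, 3.47]%, high > 3.47%) and an alarm flag on delirium
  decisions.
* **S-CAM screening** — the four-step short Confusion Assessment Method
  determination (delirium-positive ⇔ inattention AND (disorganized
  thinking OR altered consciousness), with the classic CAM variant behind
  a flag).
* **Interventions** — the three-component preventive checklist
  (orientation / environmental / risk avoidance) with a completion
  performance rate.
* **Evaluation** — repeated stratified cross-validation (default 10×2),
  macro/weighted F1, accuracy, sensitivity, specificity, rank-statistic
  AUC, and paired Wilcoxon signed-rank comparisons with exact tie-aware
  p-values and rank-biserial effect sizes.
* **Synthetic cohorts** — a planted-rule generator emulating a
  low-prevalence LCF cohort, so the whole pipeline is testable without
  patient data.
* **SUS scoring** — standard 0–100 System Usability Scale scoring with the
  68-point above-average benchmark.

Everything is data-frame-first and returns tibbles; results have
`tidy()`/`glance()` and `autoplot()` methods. A thin command-line front
end lives in `inst/cli/delirisk.R`.

## Worked example

```r
library(delirisk)

schema <- default_schema()                      # 24 binary risk factors
cohort <- generate_cohort(n = 173, seed = 7)    # synthetic LCF cohort, ~8% delirium
table(cohort$label)
#>     delirium non-delirium
#>           17          156

rules <- lem2_induce(cohort, schema)            # certain rules, deterministic
glance(rules)
#> # A tibble: 1 × 5
#>   n_rules n_delirium_rules mean_conditions mean_support mean_confidence
#> 1      21                7            4.05         8.84             100

predict_delirium(cohort[c(1, 8, 11), ], rules)
#> # A tibble: 3 × 7
#>   patient_id best_rule_id matching_degree risk_percent risk_level
#> 1 Park-001             10             100         6.94 none
#> 2 Seo-008               5             100         1.73 medium
#> 3 Choi-011              4             100         1.16 low
#> # predicted_class <chr>, alarm <lgl>
```

`risk_percent` is the matched rule's support; `Seo-008` sits exactly on the
lower tertile cut-off 1.73% and is therefore *medium* (the medium interval
is closed). Only delirium decisions raise the alarm flag — `Park-001`'s
best rule decides non-delirium, so its level is `none`.

A positive S-CAM screen then triggers the intervention checklist:

```r
assess_scam(tibble::tibble(
  step1_acute_onset = "yes", step1_fluctuation = "no",
  step2_inattention = "yes", step3_disorganized_thinking = "no",
  step4_consciousness = "lethargic"
))[, c("box1_any_yes", "box2_any_yes", "delirium_positive")]
#>   box1_any_yes box2_any_yes delirium_positive
#> 1 TRUE         TRUE         TRUE

plan <- build_plan("high", TRUE, patient_id = "Park-012")   # 22 items
plan <- mark_completed(plan, plan$item[1:10])
performance_rate(plan)
#> [1] 45.5
```

And the validation protocol over the same cohort:

```r
cv <- stratified_repeated_cv(cohort, schema, lem2_learner(), k = 2,
                             repeats = 10, seed = 1)
glance(cv)
#> # A tibble: 1 × 9
#>   n_folds repeats     k accuracy sensitivity specificity macro_f1 weighted_f1
#> 1      20      10     2     84.0        9.58        92.2     49.9        83.1
```

The low sensitivity is expected here: certain-rule classifiers generalise
poorly from 17 positive examples split across folds — which is exactly the
kind of behaviour the harness exists to expose. See the methods vignette
(`vignettes/delirium-risk-engine.Rmd`) for the model, conventions and
design decisions.

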