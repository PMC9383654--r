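---
title: "Rule-based delirium risk prediction: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based delirium risk prediction: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delirisk)
library(dplyr)
```

## The problem

Delirium — an acute, fluctuating disturbance of attention and consciousness —
is common in frail older adults but poorly recognised in long-term care
facilities (LCFs), where incidence is around 8% and specialist assessment is
scarce. delirisk implements the computational core of a clinical decision
support workflow for this setting: a transparent, rule-based risk predictor
over a small panel of categorical risk factors, a four-step Confusion
Assessment Method (short form, "S-CAM") screen, a preventive-intervention
checklist with a completion rate, and the statistical machinery to validate
the predictor by repeated stratified cross-validation.

Everything operates on ordinary tibbles, so the pieces chain with the pipe
from simulation through induction, inference, screening and planning.

## The knowledge model

A **schema** (`rf_schema()`) declares the risk factors; the shipped default
(`default_schema()`) has 24 binary factors. A **rule** is an IF–THEN
statement: a non-empty set of factor = value conditions and a class decision
(delirium / non-delirium). Over a labelled training cohort of $N$ records a
rule $r$ with condition set $C_r$ and decision $d_r$ carries

$$\mathrm{support}(r) = 100\,\frac{\#\{i : i \models C_r \wedge y_i = d_r\}}{N},
\qquad
\mathrm{confidence}(r) = 100\,\frac{\#\{i : i \models C_r \wedge y_i = d_r\}}{\#\{i : i \models C_r\}},$$

the standard class-association-rule definitions (confidence 0 when nothing
matches the antecedent). These satisfy the identity
support = confidence × coverage/100, which the test suite asserts to 1e-9.
A record that is missing a condition's factor does **not** satisfy that
condition — conservative, and consistent with an entry form that collects
only a subset (around 10) of the 24 algorithm factors.

## Inference: matching degree, tie-breaks, risk tertiles

For a record $x$ and rule $r$, the **matching degree** is the percentage of
conditions satisfied, $100\,|\{c \in C_r : x \models c\}|/|C_r|$. The engine
selects the rule with the highest matching degree; ties are broken by the
highest support × confidence product, and any residual tie by the lowest
rule id — a documented, deterministic chain (`select_best_rule()` is tested
against an exhaustive argmax oracle on a thousand random rule-base/record
pairs).

When the winning rule decides delirium, its **support** is reported as the
risk percentage and cut into tertiles: *low* below `tau_low` = 1.73%,
*medium* on the closed interval [1.73, 3.47]%, *high* above
`tau_high` = 3.47%. The defaults are the 33.3rd/66.7th percentiles of the
deployed rule supports on a 173-record cohort (1.73% ≈ 3/173,
3.47% ≈ 6/173); both are configurable in `engine_config()`. The closed
medium interval plus strict outer inequalities partition [0, 100], so every
support maps to exactly one level. A non-delirium winner yields risk level
`"none"` and no alarm; the alarm flag is raised exactly when the predicted
class is delirium, and `predict_delirium()` can append each decision to a
JSON-lines audit log. Choosing support as the displayed risk percentage is a
design decision: the tertiles are defined on support, so that is the only
scale on which the cut-offs are meaningful.

```{r inference-demo}
schema <- default_schema()
cohort <- generate_cohort(n = 173, seed = 7)
rules <- lem2_induce(cohort, schema)
glance(rules)
predict_delirium(cohort[1:5, ], rules)
```

## Rule induction: LEM2

`lem2_induce()` implements the LEM2 rough-set local-covering algorithm. For
each class it takes the **lower approximation** (records whose
indiscernibility class — identical factor vector, missing treated as its own
value — lies entirely inside the class), so induced rules are *certain*;
the upper approximation is available by argument for deliberately possible
rules. It then greedily grows condition sets: at each step it picks the
attribute–value pair covering the most remaining goal records, breaking
ties by the smallest total coverage and then schema factor/value order.
Grown rules are pruned to minimality (dropping any single condition would
break consistency) and the per-class rule set is pruned of redundant rules.
The fixed tie-break order makes induction fully deterministic: identical
cohort and configuration give an identical rule base, with the induction
parameters recorded in the rule base's provenance.

The test suite verifies the three local-covering properties — consistency,
minimality and completeness — by exhaustive enumeration over condition
subsets on toy tables (at most 10 records, 4 factors), where brute force is
feasible; minimality of a rule follows from the failure of every proper
condition subset, which the oracle checks directly.

There is no discretization step: the schema is categorical/binary by
construction. Comparator learners (decision trees, logistic regression,
and so on) are not re-implemented; `stratified_repeated_cv()` accepts any
object with a `fit`/`predict` contract, and `lem2_learner()` adapts LEM2 to
it.

## The S-CAM screen

`assess_scam()` encodes the four-step determination: delirium-positive
requires a YES on Step 2 (inattention), at least one YES in Box 1 (Steps
1–2) and at least one YES in Box 2 (Step 3 disorganized thinking, or Step 4
consciousness at any level other than *normal* — "vigilant" counts as
altered, the usual CAM convention). Since a Step-2 YES already satisfies
Box 1, the deployed rule reduces to `step2 AND (step3 OR step4 != normal)`;
this makes Box 1 logically redundant, which diverges from the classic CAM
requirement of feature 1 AND feature 2. We implement the deployed rule
verbatim as the default and expose `standard_cam = TRUE` for the classic
variant. The full 80-cell truth table is checked against the literal
boolean formula in the tests. The delirium subtype (hyperactive, hypoactive,
mixed) is a recorded, never computed, field: no decision criteria exist for
it in this workflow.

## Interventions and usability scoring

`build_plan()` issues the three-component checklist (orientation,
environmental, risk avoidance) from a shipped catalogue. The strictly
stated eligibility is high risk AND a positive screen; because the
components are preventive we default to a prevention-biased policy (high
risk OR positive screen) with `policy = "strict"` available. All three
categories are always issued together; the completion **performance rate**
is 100 × completed/total, rounded half-up to one decimal for display parity.

`sus_score()` scores the 10-item System Usability Scale. The default is
standard Brooke scoring (odd items contribute value − 1, even items
5 − value, total × 2.5), which is the only scoring consistent with the
instrument's 0–100 range and its 68-point above-average benchmark; a
`raw_sum` mode (raw sum × 2.5, range [25, 125]) is provided for
transparency toward descriptions that state the literal sum, and is
deliberately not the default.

## The evaluation harness

`stratified_repeated_cv()` runs the validation protocol: by default
10-times stratified twofold cross-validation (20 fold records). Each repeat
re-stratifies with a fresh seed derived deterministically from the master
seed; per repeat the test folds partition the cohort and per-class counts
stay within one record of proportionality. The earlier five-fold protocol
is `k = 5, repeats = 1`.

Metric conventions, each of which the tests pin down with hand-computed
values:

* **Per-class F1** = 2PR/(P+R); a class with no truths and no predictions
  contributes 0 (the common convention; configurable analyses can drop the
  class instead by filtering the confusion matrix).
* **Macro F1** is the unweighted class mean; **weighted F1** weights by
  true-class counts, the standard definition (cross-checked against
  scikit-learn on the frozen hand-worked confusion).
* **AUC** uses the Mann–Whitney rank statistic with midranks, so ties are
  handled and all-equal scores give 0.5; `pROC::auc` serves as an
  independent cross-check in the tests, not as the implementation.
* **`paired_wilcoxon()`** drops zero differences and, for up to 25 non-zero
  pairs, computes the *exact* two-sided p-value by dynamic programming over
  the null distribution of the signed-rank statistic on (possibly tied)
  midranks — the textbook exact tables do not apply under ties, and the
  implementation is verified against full $2^n$ sign-assignment
  enumeration. Beyond 25 pairs it uses the tie-corrected normal
  approximation. The reported effect size is the matched-pairs rank-biserial
  correlation $(W^+ - W^-)/(W^+ + W^-)$, chosen because it is bounded in
  [−1, 1] and standard for signed-rank comparisons.

```{r cv-demo}
cv <- stratified_repeated_cv(cohort, schema, lem2_learner(), k = 2,
                             repeats = 10, seed = 1)
glance(cv)
```

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a low-prevalence LCF cohort:
independent binary factors (default marginal 0.3), labels produced by a
planted rule mechanism, and a residual delirium probability calibrated from
the realized planted-rule coverage so overall prevalence approximates the
8.1% LCF incidence at the default n = 173. The default planted rules are
three 3-condition delirium rules over named factors; at marginal 0.3 each
fires for about 2.7% of records, so the planted coverage alone is already
near the target prevalence. Labels rule-driven rather than logistic is a
deliberate choice: it matches the discrete mechanism the engine assumes and
makes *rule recovery* well-defined, via `rule_recovery_report()` (exact
syntactic recovery, and coverage-equivalent recovery on a reference
cohort — the meaningful notion when logically equivalent rules differ
syntactically).

With `base_prevalence = 0` and `label_noise = 0` the labels are a pure
deterministic function of the planted rules; in that noiseless regime LEM2
attains 100% training accuracy and recovers every planted rule
coverage-equivalently (asserted over cohorts of n = 500 with the three
default planted rules across 10 seeds).

What the generator does **not** emulate: correlated comorbidity structure,
informative missingness, longitudinal records, or the case mix of any real
facility. Passing tests therefore demonstrate the *software* — induction
correctness, inference determinism, metric arithmetic — not clinical
validity on real patients, whose published headline performance figures
come from cohorts that are not publicly deposited and are consequently not
reproduction targets here.

## Numerical and degenerate-input choices

* Missing values never satisfy rule conditions — in matching, in
  support/confidence and in induction.
* The medium risk interval is closed on both ends; the partition property
  is property-tested over a boundary-including grid.
* Residual tie-breaks everywhere resolve to the lowest rule id; LEM2's
  inner loop resolves to schema order. No randomness is consumed outside
  the generator and the CV fold assignment, both seed-controlled.
* Performance rate rounds half-up (33.33 → 33.3, 6.25 → 6.3).
* Degenerate inputs: empty rule bases error; an all-zero confusion matrix
  errors; all-zero Wilcoxon differences return p = 1, effect 0; a
  single-class cohort induces rules for that class only, with a warning;
  an all-missing factor is ignored with a warning.

## Problem sizes in the shipped checks

The test suite runs at sizes chosen to keep brute-force oracles exact and
the whole suite fast: toy tables of at most 10 records and 4 factors for
exhaustive LEM2 verification, n = 500 across 10 seeds for planted-rule
recovery, n in the low hundreds for CV properties, 1,000 random pairs for
the best-rule argmax check, and pooled 10 × 1,000-record cohorts for the
prevalence calibration check (a 99.9% binomial interval on the pooled
count, which detects real bias of about a percentage point while being
robust to single-cohort sampling noise).

## Known limitations

* The engine is only as good as its rule base; rules induced from 173-record
  cohorts carry supports quantised to ~0.6 percentage points, so the tertile
  cut-offs should be recomputed per deployment cohort.
* LEM2 certain rules can leave inconsistent records uncovered; classification
  falls back to partial matching, which always answers but with no
  consistency guarantee.
* No continuous-feature handling, no incremental rule updating (re-induce
  instead), no comparator learners beyond the fit/predict adapter.
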