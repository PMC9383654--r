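Package: delirisk
Title: Rule-Based Delirium Risk Prediction and Prevention for Long-Term Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for rule-based clinical decision support around
    delirium in long-term care facilities: LEM2 rough-set rule induction
    from binary/categorical risk-factor cohorts, matching-degree inference
    with a support-times-confidence tie-break, tertile risk stratification
    with alarm flagging, the four-step short Confusion Assessment Method
    screening logic, multi-component preventive-intervention checklists,
    System Usability Scale scoring, a repeated stratified cross-validation
    harness with macro/weighted F1 and exact paired Wilcoxon signed-rank
    comparisons, and a synthetic cohort generator with planted rule
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
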