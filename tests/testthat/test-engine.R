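test_that("matching degree is the fraction of satisfied conditions", {
  s <- toy_schema(4)
  r4 <- rule(1, c(f1 = "yes", f2 = "yes", f3 = "yes", f4 = "yes"), "delirium")
  expect_equal(matching_degree(r4, list(f1 = "yes", f2 = "yes", f3 = "yes", f4 = "yes")), 100)
  expect_equal(matching_degree(r4, list(f1 = "yes", f2 = "yes", f3 = "yes", f4 = "no")), 75)
  # a missing factor never satisfies a condition
  r2 <- rule(1, c(f1 = "yes", f2 = "yes"), "delirium")
  expect_equal(matching_degree(r2, list(f1 = "yes", f2 = NA)), 50)
})

test_that("select_best_rule implements the documented tie-break chain", {
  s <- toy_schema(3)
  # two rules tied at 100% matching: support 2 x conf 100 = 200 beats 4 x 40 = 160
  rb <- rulebase(dplyr::bind_rows(
    rule(1, c(f1 = "yes"), "delirium", support = 2, confidence = 100),
    rule(2, c(f2 = "yes"), "non-delirium", support = 4, confidence = 40)
  ), s)
  rec <- list(f1 = "yes", f2 = "yes", f3 = "no")
  expect_equal(select_best_rule(rb, rec)$rule_id, 1L)

  # tie on matching AND product: lowest rule_id
  rb2 <- rulebase(dplyr::bind_rows(
    rule(7, c(f1 = "yes"), "delirium", support = 2, confidence = 50),
    rule(3, c(f2 = "yes"), "delirium", support = 1, confidence = 100)
  ), s)
  expect_equal(select_best_rule(rb2, rec)$rule_id, 3L)

  # single rule at the top simply wins
  rb3 <- rulebase(dplyr::bind_rows(
    rule(1, c(f1 = "yes", f2 = "yes"), "delirium", support = 1, confidence = 10),
    rule(2, c(f3 = "yes"), "non-delirium", support = 99, confidence = 99)
  ), s)
  expect_equal(select_best_rule(rb3, rec)$rule_id, 1L)

  expect_error(select_best_rule(rulebase(rb$rules[0, ], s), rec), "empty rule base")
})

test_that("select_best_rule agrees with the exhaustive argmax oracle", {
  s <- toy_schema(5)
  set.seed(42)
  for (i in 1:100) {
    rb <- random_rulebase(s, sample(2:8, 1))
    rec <- random_record(s)
    expect_equal(select_best_rule(rb, rec)$rule_id,
                 rb$rules$rule_id[oracle_best_rule(rb, rec)])
  }
})

test_that("a below-threshold best match yields the nothing-matched signal", {
  s <- toy_schema(2)
  rb <- rulebase(rule(1, c(f1 = "yes", f2 = "yes"), "delirium",
                      support = 2, confidence = 100), s)
  cfg <- engine_config(min_matching_degree = 75)
  expect_equal(nrow(select_best_rule(rb, list(f1 = "yes", f2 = "no"), cfg)), 0L)
  res <- predict_delirium(tibble::tibble(f1 = "yes", f2 = "no"), rb, cfg)
  expect_true(is.na(res$best_rule_id))
  expect_equal(res$risk_level, "none")
  expect_false(res$alarm)
})

test_that("risk stratification reproduces the tertile boundaries", {
  expect_equal(stratify_risk(c(1.00, 1.73, 3.47, 3.48)),
               c("low", "medium", "medium", "high"))
})

test_that("the three risk levels partition [0, 100]", {
  grid <- c(0, 0.5, 1.729999, 1.73, 1.730001, 2.5, 3.469999, 3.47, 3.470001,
            10, 50, 100, seq(0, 100, by = 0.37))
  lev <- stratify_risk(grid)
  expect_true(all(lev %in% c("low", "medium", "high")))  # exactly one level each
  cfg <- engine_config()
  expect_equal(lev == "low", grid < cfg$tau_low)
  expect_equal(lev == "high", grid > cfg$tau_high)
})

test_that("engine_config validates its invariants", {
  expect_error(engine_config(tau_low = 3, tau_high = 2), "tau_low < tau_high")
  expect_error(engine_config(alarm_channels = "smoke"), "unknown alarm channel")
})

test_that("adding a rule that matches worse than the winner never changes the output", {
  s <- toy_schema(4)
  set.seed(31)
  for (i in 1:30) {
    rb <- random_rulebase(s, 4)
    rec <- random_record(s, p_missing = 0)
    best <- select_best_rule(rb, rec)
    worse_fac <- names(rec)[1]
    worse_val <- if (rec[[worse_fac]] == "yes") "no" else "yes"
    extra <- rule(99, stats::setNames(worse_val, worse_fac), "delirium",
                  support = 50, confidence = 100)  # matches at 0%
    rb2 <- rulebase(dplyr::bind_rows(rb$rules, extra), s)
    expect_equal(select_best_rule(rb2, rec)$rule_id, best$rule_id)
  }
})

test_that("predict composes selection and stratification with the alarm invariants", {
  s <- toy_schema(2)
  rb <- rulebase(dplyr::bind_rows(
    rule(1, c(f1 = "yes"), "delirium", support = 4.0, confidence = 90),
    rule(2, c(f1 = "no"), "non-delirium", support = 80, confidence = 95)
  ), s)
  res <- predict_delirium(tibble::tibble(f1 = c("yes", "no"), f2 = "no"), rb)
  expect_equal(res$risk_level, c("high", "none"))
  expect_equal(res$risk_percent, c(4.0, 80))  # the matched rule's support
  expect_equal(res$alarm, c(TRUE, FALSE))
  expect_equal(res$predicted_class, c("delirium", "non-delirium"))
  expect_error(predict_delirium(tibble::tibble(f1 = "yes"), rulebase(rb$rules[0, ], s)),
               "empty rule base")
})

test_that("risk_level is none iff non-delirium, and alarm iff delirium (random property)", {
  s <- toy_schema(4)
  set.seed(77)
  for (i in 1:25) {
    rb <- random_rulebase(s, 5)
    res <- predict_delirium(random_record(s), rb)
    expect_equal(res$risk_level == "none", res$predicted_class != "delirium")
    expect_equal(res$alarm, res$predicted_class == "delirium")
  }
})

test_that("predictions are appended to the audit log as JSON lines", {
  s <- toy_schema(2)
  rb <- rulebase(rule(1, c(f1 = "yes"), "delirium", support = 2, confidence = 100), s)
  log <- withr::local_tempfile(fileext = ".jsonl")
  predict_delirium(tibble::tibble(patient_id = "Kim-001", f1 = "yes", f2 = "no"),
                   rb, audit_log = log)
  entry <- jsonlite::fromJSON(readLines(log))
  expect_equal(entry$patient_id, "Kim-001")
  expect_true(entry$alarm)
  expect_setequal(entry$alarm_channels, c("screen", "vibration"))
})
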