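test_that("macro and weighted F1 reproduce the hand-worked confusion", {
  # truth in rows, prediction in columns; delirium TP=1, FN=1, FP=0, TN=97
  cm <- matrix(c(1, 1, 0, 97), nrow = 2, byrow = TRUE,
               dimnames = list(c("delirium", "non-delirium"),
                               c("delirium", "non-delirium")))
  # per-class F1: delirium 2/3 = 66.67, non-delirium 194/195 = 99.49
  expect_equal(macro_f1(cm), 100 * (2 / 3 + 194 / 195) / 2)
  expect_equal(round(macro_f1(cm), 2), 83.08)
  # weighted by true-class counts (2 and 97); frozen against
  # sklearn f1_score(average = "weighted") on the same confusion
  expect_equal(weighted_f1(cm), 100 * (2 * 2 / 3 + 97 * 194 / 195) / 99)
  expect_equal(weighted_f1(cm), 98.8241388241388, tolerance = 1e-10)
})

test_that("F1 degenerate conventions hold", {
  diag_cm <- diag(c(5, 9))
  expect_equal(macro_f1(diag_cm), 100)
  expect_equal(weighted_f1(diag_cm), 100)
  # a class with zero truths and zero predictions contributes F1 = 0 to macro
  cm3 <- matrix(0, 3, 3)
  cm3[1, 1] <- 4; cm3[2, 2] <- 4
  expect_equal(macro_f1(cm3), 100 * (1 + 1 + 0) / 3)
  expect_error(macro_f1(matrix(0, 2, 2)), "all-zero")
  expect_error(weighted_f1(matrix(0, 2, 2)), "all-zero")
})

test_that("macro equals weighted exactly when class counts are equal", {
  cm <- matrix(c(7, 3, 2, 8), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(macro_f1(cm), weighted_f1(cm))
})

test_that("binary metrics are plain confusion arithmetic", {
  got <- binary_metrics(tp = 3, fn = 1, fp = 2, tn = 4)
  expect_equal(got$sensitivity, 75)
  expect_equal(got$specificity, 100 * 4 / 6)
  expect_equal(got$accuracy, 70)
  expect_true(is.na(binary_metrics(0, 0, 2, 4)$sensitivity))
})

test_that("rank AUC handles the limiting cases and agrees with pROC", {
  lab <- c(rep("delirium", 4), rep("non-delirium", 8))
  expect_equal(auc_rank(as.numeric(lab == "delirium"), lab), 1)
  expect_equal(auc_rank(rep(0.3, 12), lab), 0.5)
  expect_error(auc_rank(1:4, rep("delirium", 4)), "both classes")
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:10) {
    sc <- round(stats::runif(30), 1)  # rounding forces ties
    la <- sample(c("delirium", "non-delirium"), 30, replace = TRUE,
                 prob = c(0.3, 0.7))
    if (length(unique(la)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = la, predictor = sc, levels = c("non-delirium", "delirium"),
      direction = "<", quiet = TRUE)))
    expect_equal(auc_rank(sc, la), ref)
  }
})

test_that("the paired Wilcoxon matches sign-assignment enumeration, ties included", {
  # hand case: differences +1, +2, +3, -1, +4, +5 (tied |d| = 1)
  a <- c(2, 3, 4, 1, 6, 9)
  b <- c(1, 1, 1, 2, 2, 4)
  got <- paired_wilcoxon(a, b)
  expect_equal(got$wilcoxon_statistic, 19.5)  # midranks 1.5,3,4,(1.5),5,6
  expect_equal(got$p_value, oracle_signed_rank_p(a - b))
  expect_equal(got$p_value, 0.09375)
  # random small cases with ties and zeros against the 2^n oracle
  set.seed(23)
  for (i in 1:20) {
    d <- sample(-4:4, sample(5:10, 1), replace = TRUE)
    if (all(d == 0)) next
    x <- cumsum(rep(1, length(d))); y <- x - d
    expect_equal(paired_wilcoxon(x, y)$p_value, oracle_signed_rank_p(d))
  }
})

test_that("the exact path agrees with stats::wilcox.test when ties are absent", {
  set.seed(14)
  for (i in 1:10) {
    d <- sample(setdiff(-40:40, 0), 12)  # distinct |d| w.h.p.; enforce below
    if (anyDuplicated(abs(d))) next
    x <- seq_along(d); y <- x - d
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    got <- paired_wilcoxon(x, y)
    expect_equal(got$wilcoxon_statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
})

test_that("effect size is the matched-pairs rank-biserial correlation", {
  # a dominates b in all 20 pairs -> effect 1
  a <- 21:40; b <- 1:20
  got <- paired_wilcoxon(a, b)
  expect_equal(got$effect_size, 1)
  expect_equal(paired_wilcoxon(b, a)$effect_size, -1)
  # identical scores: degenerate result
  same <- paired_wilcoxon(a, a)
  expect_equal(same$p_value, 1)
  expect_equal(same$effect_size, 0)
  # bounded in [-1, 1] on random input
  set.seed(3)
  for (i in 1:10) {
    x <- stats::rnorm(15); y <- stats::rnorm(15)
    e <- paired_wilcoxon(x, y)$effect_size
    expect_true(abs(e) <= 1)
  }
})

test_that("large-sample path uses the tie-corrected normal approximation", {
  set.seed(6)
  x <- stats::rnorm(40, mean = 0.3); y <- stats::rnorm(40)
  got <- paired_wilcoxon(x, y)
  expect_match(got$method, "normal")
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("10x2 stratified CV yields 20 folds partitioning the cohort per repeat", {
  s <- default_schema()
  co <- generate_cohort(n = 120, base_prevalence = 0.15, seed = 33)
  # tag records so fold membership can be tracked through a learner
  learner <- list(
    fit = function(data, schema) data,
    predict = function(model, newdata) rep("non-delirium", nrow(newdata))
  )
  cv <- stratified_repeated_cv(co, s, learner, k = 2, repeats = 10, seed = 5)
  expect_equal(nrow(cv), 20L)
  expect_equal(sort(unique(cv$repeat_index)), 1:10)
  # per repeat the two test folds partition the cohort
  sizes <- dplyr::summarise(dplyr::group_by(cv, repeat_index), n = sum(n_test))
  expect_true(all(sizes$n == nrow(co)))
  # stratification: per-fold positives within one record of proportionality
  n_pos <- sum(co$label == "delirium")
  expect_true(all(abs((cv$tp + cv$fn) - n_pos * cv$n_test / nrow(co)) <= 1))
  # determinism
  cv2 <- stratified_repeated_cv(co, s, learner, k = 2, repeats = 10, seed = 5)
  expect_equal(as.data.frame(cv), as.data.frame(cv2))
  # confusion counts sum to the fold size
  expect_equal(cv$tp + cv$fn + cv$fp + cv$tn, cv$n_test)
})

test_that("a perfect learner attains macro F1 = 100 on every fold", {
  s <- default_schema()
  co <- generate_cohort(n = 200, base_prevalence = 0, seed = 12)
  planted <- default_planted_rules(s)
  oracle_learner <- list(
    fit = function(data, schema) planted,
    predict = function(model, newdata) {
      hit <- rep(FALSE, nrow(newdata))
      for (i in seq_len(nrow(model$rules))) {
        hit <- hit | delirisk:::rule_matches(model$rules$conditions[[i]], newdata)
      }
      ifelse(hit, "delirium", "non-delirium")
    }
  )
  cv <- stratified_repeated_cv(co, s, oracle_learner, seed = 2)
  expect_true(all(cv$macro_f1 == 100))
  expect_true(all(cv$weighted_f1 == 100))
})

test_that("a class smaller than k aborts with the class named", {
  s <- toy_schema(2)
  co <- toy_cohort(c("11", "00", "01", "10"),
                   c("delirium", rep("non-delirium", 3)), s)
  expect_error(stratified_repeated_cv(co, s, lem2_learner(), k = 2),
               "delirium.*fewer than")
})

test_that("compare_models pairs folds and reports the Wilcoxon comparison", {
  s <- default_schema()
  co <- generate_cohort(n = 120, base_prevalence = 0.15, seed = 33)
  maj <- list(fit = function(data, schema) NULL,
              predict = function(model, newdata) rep("non-delirium", nrow(newdata)))
  cv_lem2 <- stratified_repeated_cv(co, s, lem2_learner(), seed = 5)
  cv_maj <- stratified_repeated_cv(co, s, maj, seed = 5)
  cmp <- compare_models(cv_lem2, cv_maj, metric = "macro_f1",
                        model_a = "lem2", model_b = "majority")
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  expect_true(abs(cmp$effect_size) <= 1)
  expect_equal(cmp$metric, "macro_f1")
  # LEM2 recovers planted structure, so it should dominate the majority vote
  expect_gt(mean(cv_lem2$macro_f1), mean(cv_maj$macro_f1))
})
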