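#' Confusion matrix over a fixed class set
#'
#' @param truth,pred Character vectors of true and predicted classes.
#' @param classes Class levels (rows = truth, columns = prediction).
#' @return An integer matrix with `classes` as dimnames.
#' @export
confusion_matrix <- function(truth, pred, classes = sort(unique(c(truth, pred)))) {
  stopifnot(length(truth) == length(pred))
  table(factor(truth, levels = classes), factor(pred, levels = classes)) |>
    unclass()
}

per_class_f1 <- function(cm) {
  # F1 per class; a class with no predictions and no truths contributes 0
  purrr::map_dbl(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    denom <- 2 * tp + sum(cm[, i]) - tp + sum(cm[i, ]) - tp  # 2TP + FP + FN
    if (denom == 0) 0 else 2 * tp / denom
  })
}

#' Macro-averaged and weighted-average F1 (percent)
#'
#' Per-class F1 = 2PR/(P+R); a degenerate class (no truths and no
#' predictions) contributes F1 = 0. Macro is the unweighted mean across
#' classes; weighted averages per-class F1 with true-class counts, so it
#' is dominated by the majority class in imbalanced cohorts. The two
#' coincide exactly when the true class counts are equal.
#'
#' @param cm A square confusion matrix (truth in rows, prediction in
#'   columns), e.g. from [confusion_matrix()].
#' @return Percentage in `[0, 100]`.
#' @export
macro_f1 <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) == 0) stop("all-zero confusion matrix", call. = FALSE)
  100 * mean(per_class_f1(cm))
}

#' @rdname macro_f1
#' @export
weighted_f1 <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) == 0) stop("all-zero confusion matrix", call. = FALSE)
  w <- rowSums(cm)
  100 * sum(per_class_f1(cm) * w) / sum(w)
}

#' Binary classification metrics from confusion counts
#'
#' @param tp,fn,fp,tn Confusion counts with delirium (the positive class)
#'   defining sensitivity.
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`
#'   (percent; `NA` where the denominator is empty).
#' @export
binary_metrics <- function(tp, fn, fp, tn) {
  div <- function(a, b) if (b == 0) NA_real_ else 100 * a / b
  tibble::tibble(
    accuracy = div(tp + tn, tp + fn + fp + tn),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp)
  )
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation with midranks, so tied scores are handled by
#' the usual tie correction (all scores equal gives 0.5).
#'
#' @param scores Numeric scores, larger meaning more delirium-like.
#' @param labels Class labels.
#' @param positive The positive class. Default `"delirium"`.
#' @return AUC as a fraction in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels, positive = "delirium") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores)  # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exact null distribution of the signed-rank statistic W+ over sign
# assignments, supporting tied (half-integer) midranks: dynamic programming
# over doubled ranks. Counts stay below 2^n <= 2^25, exact in doubles.
signed_rank_exact_p <- function(w, r) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[s+1] = #assignments with doubled sum s
  counts[1L] <- 1
  for (x in r2) {
    shifted <- c(numeric(x), counts[seq_len(total + 1L - x)])
    counts <- counts + shifted
  }
  mu <- total / 2
  dev <- abs(2 * w - mu)  # doubled scale
  s <- seq(0L, total)
  sum(counts[abs(s - mu) >= dev - 1e-9]) / 2^length(r2)
}

#' Paired Wilcoxon signed-rank test with rank-biserial effect size
#'
#' Two-sided signed-rank test on paired scores. Zero differences are
#' dropped. For up to 25 non-zero pairs the p-value is exact, computed by
#' enumerating the null distribution of the statistic over sign
#' assignments (valid under ties, where the textbook tables are not);
#' beyond that a tie-corrected normal approximation is used. The effect
#' size is the matched-pairs rank-biserial correlation
#' `(W+ - W-) / (W+ + W-)`, in `[-1, 1]`: 1 when a dominates b in every
#' pair. All differences zero gives the degenerate result p = 1, effect 0.
#'
#' @param scores_a,scores_b Equal-length numeric vectors (>= 5 pairs) of
#'   paired per-fold scores.
#' @param model_a,model_b Labels carried into the result.
#' @param metric Label for the compared metric.
#' @return A one-row tibble: `model_a`, `model_b`, `metric`,
#'   `wilcoxon_statistic` (W+), `p_value`, `effect_size`, `n_nonzero`,
#'   `method`.
#' @export
paired_wilcoxon <- function(scores_a, scores_b, model_a = "a", model_b = "b",
                            metric = "score") {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 5)
  d <- scores_a - scores_b
  d <- d[d != 0]
  n <- length(d)
  out <- function(w, p, eff, method) tibble::tibble(
    model_a = model_a, model_b = model_b, metric = metric,
    wilcoxon_statistic = w, p_value = p, effect_size = eff,
    n_nonzero = n, method = method
  )
  if (n == 0L) return(out(0, 1, 0, "degenerate (all differences zero)"))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  total <- sum(r)
  effect <- (2 * w_plus - total) / total
  if (n <= 25L) {
    p <- signed_rank_exact_p(w_plus, r)
    method <- "exact (sign-assignment enumeration)"
  } else {
    mu <- total / 2
    sigma2 <- sum(r^2) / 4  # = n(n+1)(2n+1)/24 - tie correction, via midranks
    z <- (w_plus - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie-corrected"
  }
  out(w_plus, min(p, 1), effect, method)
}

#' A learner adapter for LEM2
#'
#' Wraps [lem2_induce()] and [classify()] into the fit/predict contract
#' [stratified_repeated_cv()] expects, so LEM2 can be cross-validated like
#' any external learner. The optional score (for AUC) is the maximum
#' matching degree over the delirium rules, a continuous proxy for how
#' close a record is to firing a delirium rule.
#'
#' @param mode Classification mode passed to [classify()].
#' @param ... Further arguments to [lem2_induce()].
#' @return A list with elements `fit(data, schema)`, `predict(model,
#'   newdata)` and `score(model, newdata)`.
#' @export
lem2_learner <- function(mode = "strict", ...) {
  dots <- list(...)
  list(
    fit = function(data, schema) {
      do.call(lem2_induce, c(list(cohort = data, schema = schema), dots))
    },
    predict = function(model, newdata) classify(model, newdata, mode = mode),
    score = function(model, newdata) {
      pos <- model$schema$target_levels[1]
      del <- which(model$rules$decision == pos)
      if (length(del) == 0L) return(rep(0, nrow(newdata)))
      purrr::map_dbl(seq_len(nrow(newdata)), function(i) {
        max(purrr::map_dbl(del, function(j)
          matching_degree(model$rules[j, ], newdata[i, , drop = FALSE])))
      })
    }
  )
}

#' Repeated stratified k-fold cross-validation
#'
#' The validation protocol used for the prediction algorithm: by default
#' 10-times stratified twofold cross-validation (20 fold records). Each
#' repeat draws a fresh stratified partition from a seed derived from the
#' master seed, so every record appears in exactly one test fold per
#' repeat and class proportions per fold stay within one record of the
#' cohort's. The earlier five-fold protocol is the same operation with
#' `k = 5, repeats = 1`.
#'
#' @param data Labelled cohort tibble.
#' @param schema The governing [rf_schema()].
#' @param learner A list with `fit(data, schema) -> model` and
#'   `predict(model, newdata) -> classes`; an optional `score(model,
#'   newdata)` enables per-fold AUC. See [lem2_learner()].
#' @param k Folds per repeat (default 2).
#' @param repeats Repeats (default 10).
#' @param seed Master seed; the run is fully deterministic given it.
#' @return A tibble of class `delirisk_cv`, one row per fold x repeat:
#'   `repeat_index`, `fold_index`, `n_test`, confusion counts `tp`, `fn`,
#'   `fp`, `tn` (positive class = the schema's first target level),
#'   `accuracy`, `sensitivity`, `specificity`, `macro_f1`, `weighted_f1`,
#'   `auc` (`NA` without a score function).
#' @export
stratified_repeated_cv <- function(data, schema, learner, k = 2, repeats = 10,
                                   seed = 1) {
  lab <- data[[schema$target_name]]
  if (is.null(lab) || anyNA(lab)) stop("cross-validation needs a fully labelled cohort",
                                       call. = FALSE)
  classes <- intersect(schema$target_levels, unique(lab))
  small <- classes[purrr::map_int(classes, function(cl) sum(lab == cl)) < k]
  if (length(small)) {
    stop("class `", small[1], "` has fewer than k = ", k, " records", call. = FALSE)
  }
  positive <- schema$target_levels[1]
  set.seed(seed)
  repeat_seeds <- sample.int(2^31 - 1, repeats)
  rows <- list()
  for (r in seq_len(repeats)) {
    set.seed(repeat_seeds[r])
    fold_of <- integer(nrow(data))
    for (cl in classes) {
      idx <- sample(which(lab == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    for (f in seq_len(k)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      model <- learner$fit(data[train, , drop = FALSE], schema)
      pred <- learner$predict(model, data[test, , drop = FALSE])
      cm <- confusion_matrix(lab[test], pred, classes = schema$target_levels)
      tp <- cm[positive, positive]
      fn <- sum(cm[positive, ]) - tp
      fp <- sum(cm[, positive]) - tp
      tn <- sum(cm) - tp - fn - fp
      auc <- NA_real_
      if (!is.null(learner$score) &&
          length(unique(lab[test])) > 1) {
        auc <- auc_rank(learner$score(model, data[test, , drop = FALSE]),
                        lab[test], positive = positive)
      }
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(repeat_index = r, fold_index = f, n_test = length(test),
                       tp = tp, fn = fn, fp = fp, tn = tn),
        binary_metrics(tp, fn, fp, tn),
        tibble::tibble(macro_f1 = macro_f1(cm), weighted_f1 = weighted_f1(cm),
                       auc = auc)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("delirisk_cv", class(out))
  out
}

#' Compare two cross-validated models fold-by-fold
#'
#' Pairs the per-fold F1 scores of two [stratified_repeated_cv()] results
#' (matched on repeat and fold) and runs [paired_wilcoxon()].
#'
#' @param cv_a,cv_b `delirisk_cv` tibbles from the same cohort, seed and
#'   protocol.
#' @param metric `"macro_f1"` or `"weighted_f1"`.
#' @param model_a,model_b Labels for the report.
#' @return The one-row comparison tibble from [paired_wilcoxon()].
#' @export
compare_models <- function(cv_a, cv_b, metric = c("macro_f1", "weighted_f1"),
                           model_a = "model_a", model_b = "model_b") {
  metric <- match.arg(metric)
  key_a <- paste(cv_a$repeat_index, cv_a$fold_index)
  key_b <- paste(cv_b$repeat_index, cv_b$fold_index)
  if (!identical(sort(key_a), sort(key_b))) {
    stop("fold structures differ; comparisons must pair identical folds", call. = FALSE)
  }
  b <- cv_b[match(key_a, key_b), ]
  paired_wilcoxon(cv_a[[metric]], b[[metric]],
                  model_a = model_a, model_b = model_b, metric = metric)
}
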