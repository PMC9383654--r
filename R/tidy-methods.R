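#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a rule base into one row per condition
#'
#' @param x A [rulebase()].
#' @param ... Unused.
#' @return A tibble: `rule_id`, `factor`, `value`, `decision`, `support`,
#'   `confidence`.
#' @method tidy delirisk_rulebase
#' @export
tidy.delirisk_rulebase <- function(x, ...) {
  tidyr::unnest(x$rules, "conditions")[
    , c("rule_id", "factor", "value", "decision", "support", "confidence")]
}

#' One-row summary of a rule base
#'
#' @param x A [rulebase()].
#' @param ... Unused.
#' @return A tibble: `n_rules`, `n_delirium_rules`, `mean_conditions`,
#'   `mean_support`, `mean_confidence`.
#' @method glance delirisk_rulebase
#' @export
glance.delirisk_rulebase <- function(x, ...) {
  pos <- x$schema$target_levels[1]
  tibble::tibble(
    n_rules = nrow(x$rules),
    n_delirium_rules = sum(x$rules$decision == pos),
    mean_conditions = mean(purrr::map_int(x$rules$conditions, nrow)),
    mean_support = mean(x$rules$support),
    mean_confidence = mean(x$rules$confidence)
  )
}

#' One-row summary of a cross-validation run
#'
#' @param x A `delirisk_cv` tibble from [stratified_repeated_cv()].
#' @param ... Unused.
#' @return Means over folds of accuracy, sensitivity, specificity,
#'   macro/weighted F1 and AUC, plus fold counts.
#' @method glance delirisk_cv
#' @export
glance.delirisk_cv <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x),
    repeats = max(x$repeat_index),
    k = max(x$fold_index),
    accuracy = mean(x$accuracy, na.rm = TRUE),
    sensitivity = mean(x$sensitivity, na.rm = TRUE),
    specificity = mean(x$specificity, na.rm = TRUE),
    macro_f1 = mean(x$macro_f1),
    weighted_f1 = mean(x$weighted_f1),
    auc = mean(x$auc, na.rm = TRUE)
  )
}

#' Plot rule support against confidence
#'
#' Scatter of the rule base's rules in support/confidence space with the
#' configured risk-tertile cut-offs drawn as vertical references.
#'
#' @param object A [rulebase()].
#' @param config An [engine_config()] supplying the cut-offs.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot delirisk_rulebase
#' @export
autoplot.delirisk_rulebase <- function(object, config = engine_config(), ...) {
  d <- object$rules
  ggplot2::ggplot(d, ggplot2::aes(x = .data$support, y = .data$confidence,
                                  colour = .data$decision)) +
    ggplot2::geom_vline(xintercept = c(config$tau_low, config$tau_high),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "support (%)", y = "confidence (%)",
                  title = "Rule base in support/confidence space",
                  subtitle = "dashed lines: risk-tertile cut-offs") +
    ggplot2::theme_minimal()
}

#' Plot per-fold F1 distributions of a cross-validation run
#'
#' @param object A `delirisk_cv` tibble.
#' @param ... Unused.
#' @return A ggplot object: boxplots of macro and weighted F1 over folds.
#' @method autoplot delirisk_cv
#' @export
autoplot.delirisk_cv <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("repeat_index", "fold_index", "macro_f1", "weighted_f1")],
    c("macro_f1", "weighted_f1"),
    names_to = "metric", values_to = "f1"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$f1)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "F1 (%)",
                  title = "Per-fold F1 across the repeated stratified CV") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
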