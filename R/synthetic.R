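#' Default planted rule set for synthetic cohorts
#'
#' Three 3-condition delirium rules over the named factors of
#' [default_schema()]. With factor marginals of 0.3 each rule fires for
#' about 2.7% of records, so the three together cover roughly 7.9% — on
#' the order of the 8.1% delirium incidence reported for long-term care
#' facilities — leaving only a small residual to top up.
#'
#' @param schema Schema the rules must validate against. Default
#'   [default_schema()].
#' @return A [rulebase()] with three delirium rules (no support/confidence
#'   yet; compute them against a cohort with [add_rule_stats()]).
#' @export
default_planted_rules <- function(schema = default_schema()) {
  rulebase(dplyr::bind_rows(
    rule(1L, c(dehydration = "yes", infection = "yes", sleep_disorder = "yes"),
         "delirium"),
    rule(2L, c(age_65_or_over = "yes", abnormal_bun = "yes", hypoxia = "yes"),
         "delirium"),
    rule(3L, c(disease_severity = "yes", nutritional_imbalance = "yes", pain = "yes"),
         "delirium")
  ), schema, provenance = list(origin = "synthetic planted rules"))
}

#' Generate a synthetic labelled cohort with planted rule structure
#'
#' Emulates a low-prevalence binary-feature long-term-care cohort whose
#' labels are produced by a known (planted) rule mechanism, so induction
#' and inference can be tested end-to-end without patient data. Factor
#' values are drawn independently per factor marginal; a record fully
#' satisfying any planted delirium rule is labelled delirium; the
#' remaining records are labelled delirium with a residual probability
#' calibrated so the realized overall prevalence approximates
#' `base_prevalence`; finally each label flips with probability
#' `label_noise`. With `base_prevalence = 0` and `label_noise = 0` labels
#' are a pure deterministic function of the planted rules (the noiseless
#' regime used for rule-recovery checks).
#'
#' Defaults mirror the cohort the engine was built around: n = 173
#' residents, 24 binary factors, 8.1% delirium incidence.
#'
#' @param n Cohort size. Default 173.
#' @param schema An [rf_schema()]. Default [default_schema()].
#' @param planted_rules A [rulebase()] of delirium rules driving labels.
#'   Default [default_planted_rules()].
#' @param base_prevalence Target overall delirium fraction. Default 0.081.
#' @param label_noise Probability each final label is flipped, in
#'   `[0, 0.5]`. Default 0.
#' @param factor_marginals Per-factor probability of the positive
#'   (last-listed) value, recycled across factors. Default 0.3.
#' @param seed Integer seed; the cohort is deterministic given it.
#' @return A labelled cohort tibble with `patient_id` (surname-style
#'   pseudonyms), one column per factor, and the target column.
#' @export
generate_cohort <- function(n = 173, schema = default_schema(),
                            planted_rules = default_planted_rules(schema),
                            base_prevalence = 0.081, label_noise = 0,
                            factor_marginals = 0.3, seed = 1) {
  stopifnot(n >= 1, base_prevalence >= 0, base_prevalence <= 1,
            label_noise >= 0, label_noise <= 0.5,
            all(factor_marginals >= 0 & factor_marginals <= 1))
  for (i in seq_len(nrow(planted_rules$rules))) {
    cond <- planted_rules$rules$conditions[[i]]
    bad <- setdiff(cond$factor, schema_factor_names(schema))
    if (length(bad)) stop("planted rule references unknown factor: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  fac <- schema_factor_names(schema)
  p <- rep_len(factor_marginals, length(fac))
  cols <- purrr::map2(fac, p, function(f, pf) {
    vals <- allowed_values(schema, f)
    k <- length(vals)
    if (k == 2L) {
      # binary: last value ("yes") drawn with the marginal probability
      vals[1L + stats::rbinom(n, 1L, pf)]
    } else {
      # categorical: positive value with pf, the rest uniform
      pos <- stats::rbinom(n, 1L, pf) == 1L
      out <- sample(vals[-k], n, replace = TRUE)
      out[pos] <- vals[k]
      out
    }
  })
  names(cols) <- fac
  data <- tibble::as_tibble(cols)

  pos_class <- schema$target_levels[1]
  neg_class <- schema$target_levels[2]
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(planted_rules$rules))) {
    if (planted_rules$rules$decision[i] != pos_class) next
    covered <- covered | rule_matches(planted_rules$rules$conditions[[i]], data)
  }
  label <- ifelse(covered, pos_class, neg_class)
  n_cov <- sum(covered)
  if (n_cov < n) {
    residual <- max(0, (base_prevalence * n - n_cov) / (n - n_cov))
    extra <- !covered & stats::runif(n) < residual
    label[extra] <- pos_class
  }
  if (label_noise > 0) {
    flip <- stats::runif(n) < label_noise
    label[flip] <- ifelse(label[flip] == pos_class, neg_class, pos_class)
  }

  surnames <- c("Kim", "Lee", "Park", "Choi", "Jung", "Kang", "Cho", "Yoon",
                "Jang", "Lim", "Han", "Oh", "Seo", "Shin", "Kwon", "Hwang")
  data <- dplyr::mutate(
    data,
    patient_id = sprintf("%s-%03d", sample(surnames, n, replace = TRUE), seq_len(n)),
    .before = 1
  )
  data[[schema$target_name]] <- label
  data
}

#' Compare a planted rule set with an induced one
#'
#' For each planted rule, reports whether the induced base contains (a) a
#' rule with an identical condition set and decision (exact recovery) and
#' (b) a rule with the same decision covering exactly the same records of
#' a reference cohort (coverage-equivalent recovery — the meaningful
#' notion when logically equivalent rules differ syntactically).
#'
#' @param planted,induced [rulebase()]s over the same schema (factor names
#'   must agree).
#' @param reference A cohort tibble on which coverage is compared.
#' @return A tibble with one row per planted rule: `rule_id`, `decision`,
#'   `n_covered` (on the reference), `exact`, `coverage_equivalent`.
#' @export
rule_recovery_report <- function(planted, induced, reference) {
  if (!identical(schema_factor_names(planted$schema),
                 schema_factor_names(induced$schema))) {
    stop("planted and induced rule bases use different schemas", call. = FALSE)
  }
  cond_key <- function(cond) {
    o <- order(cond$factor)
    paste(cond$factor[o], cond$value[o], sep = "=", collapse = "&")
  }
  ind_keys <- purrr::map_chr(induced$rules$conditions, cond_key)
  ind_cover <- purrr::map(induced$rules$conditions, rule_matches, data = reference)
  purrr::map(seq_len(nrow(planted$rules)), function(i) {
    cond <- planted$rules$conditions[[i]]
    dec <- planted$rules$decision[i]
    cov <- rule_matches(cond, reference)
    same_dec <- induced$rules$decision == dec
    tibble::tibble(
      rule_id = planted$rules$rule_id[i],
      decision = dec,
      n_covered = sum(cov),
      exact = any(same_dec & ind_keys == cond_key(cond)),
      coverage_equivalent = any(same_dec &
                                  purrr::map_lgl(ind_cover, identical, y = cov))
    )
  }) |>
    dplyr::bind_rows()
}
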