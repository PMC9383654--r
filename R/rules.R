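#' Build a single classification rule
#'
#' A rule is an IF-THEN statement over risk factors: if every condition is
#' satisfied the rule proposes its decision. Support and confidence are
#' percentages over a labelled training cohort (see
#' [compute_support_confidence()]); the inference engine uses
#' support x confidence to break matching-degree ties and support alone
#' to stratify delirium risk.
#'
#' @param rule_id Positive integer identifier, unique within a rule base.
#' @param conditions Named character vector (`c(factor = value, ...)`) or a
#'   data frame with columns `factor` and `value`. Must be non-empty with
#'   no duplicate factors.
#' @param decision The target value the rule concludes.
#' @param support,confidence Percentages in `[0, 100]`, or `NA` until
#'   computed against a cohort.
#' @return A one-row tibble with a `conditions` list column.
#' @export
rule <- function(rule_id, conditions, decision, support = NA_real_,
                 confidence = NA_real_) {
  if (is.data.frame(conditions)) {
    cond <- tibble::tibble(factor = as.character(conditions$factor),
                           value = as.character(conditions$value))
  } else {
    cond <- tibble::tibble(factor = names(conditions),
                           value = as.character(conditions))
  }
  if (nrow(cond) == 0L) stop("a rule needs at least one condition", call. = FALSE)
  if (anyDuplicated(cond$factor)) {
    stop("duplicate factor within one rule: ",
         paste(unique(cond$factor[duplicated(cond$factor)]), collapse = ", "),
         call. = FALSE)
  }
  if (!(is.na(support) || (support >= 0 && support <= 100)) ||
      !(is.na(confidence) || (confidence >= 0 && confidence <= 100))) {
    stop("support and confidence must lie in [0, 100]", call. = FALSE)
  }
  if (rule_id < 1 || rule_id != as.integer(rule_id)) {
    stop("rule_id must be a positive integer", call. = FALSE)
  }
  tibble::tibble(
    rule_id = as.integer(rule_id),
    conditions = list(cond),
    decision = as.character(decision),
    support = as.numeric(support),
    confidence = as.numeric(confidence)
  )
}

#' Assemble a rule base
#'
#' The rule base is the app's JSON-serializable knowledge store: the rules,
#' the schema they are valid against, and free-text provenance (induction
#' parameters, origin).
#'
#' @param rules A tibble of rules (rows as produced by [rule()], usually
#'   `dplyr::bind_rows()` of several).
#' @param schema The governing [rf_schema()].
#' @param provenance A named list of free-form metadata.
#' @return An object of class `delirisk_rulebase`.
#' @export
rulebase <- function(rules, schema, provenance = list()) {
  rules <- tibble::as_tibble(rules)
  if (anyDuplicated(rules$rule_id)) {
    stop("duplicate rule_id: ",
         paste(unique(rules$rule_id[duplicated(rules$rule_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(rules))) {
    cond <- rules$conditions[[i]]
    for (j in seq_len(nrow(cond))) {
      f <- cond$factor[j]
      if (!f %in% schema_factor_names(schema)) {
        stop("rule ", rules$rule_id[i], " references unknown factor `", f, "`",
             call. = FALSE)
      }
      if (!cond$value[j] %in% allowed_values(schema, f)) {
        stop("rule ", rules$rule_id[i], ": value `", cond$value[j],
             "` not allowed for factor `", f, "`", call. = FALSE)
      }
    }
    if (!rules$decision[i] %in% schema$target_levels) {
      stop("rule ", rules$rule_id[i], ": unknown decision `",
           rules$decision[i], "`", call. = FALSE)
    }
  }
  structure(list(rules = rules, schema = schema, provenance = provenance),
            class = "delirisk_rulebase")
}

#' @export
print.delirisk_rulebase <- function(x, ...) {
  cat("<delirisk_rulebase> ", nrow(x$rules), " rule(s)\n", sep = "")
  tab <- dplyr::mutate(x$rules,
                       "if" = purrr::map_chr(.data$conditions, function(cc)
                         paste0(cc$factor, "=", cc$value, collapse = " & ")),
                       .keep = "unused", .after = "rule_id")
  print(tab, n = 10)
  invisible(x)
}

#' Number of rules in a rule base
#' @param rb A [rulebase()].
#' @return Integer count.
#' @export
n_rules <- function(rb) nrow(rb$rules)

# Which records satisfy every condition of `cond`? NA never satisfies.
rule_matches <- function(cond, data) {
  ok <- rep(TRUE, nrow(data))
  for (j in seq_len(nrow(cond))) {
    col <- data[[cond$factor[j]]]
    ok <- ok & !is.na(col) & col == cond$value[j]
  }
  ok
}

#' Support and confidence of a rule over a labelled cohort
#'
#' Standard class-association-rule definitions over the training cohort:
#' support is the joint frequency of antecedent and consequent as a
#' percentage of all records; confidence is the conditional frequency of
#' the consequent among records satisfying the antecedent (0 when no
#' record satisfies the conditions). A record missing (`NA`) on any
#' condition factor does not satisfy that condition.
#'
#' @param rule A one-row rule tibble (from [rule()] or a rule-base row).
#' @param cohort A labelled cohort tibble.
#' @param schema The governing [rf_schema()].
#' @return A one-row tibble with `support`, `confidence` and `coverage`
#'   (percentage of records satisfying the conditions), all in `[0, 100]`.
#' @export
compute_support_confidence <- function(rule, cohort, schema) {
  lab <- cohort[[schema$target_name]]
  if (is.null(lab) || all(is.na(lab))) {
    stop("cohort is unlabelled; support/confidence need the `",
         schema$target_name, "` column", call. = FALSE)
  }
  cond <- rule$conditions[[1]]
  m <- rule_matches(cond, cohort)
  hit <- m & !is.na(lab) & lab == rule$decision
  n <- nrow(cohort)
  tibble::tibble(
    support = 100 * sum(hit) / n,
    confidence = if (any(m)) 100 * sum(hit) / sum(m) else 0,
    coverage = 100 * sum(m) / n
  )
}

#' Recompute support and confidence for every rule in a base
#'
#' @param rb A [rulebase()].
#' @param cohort A labelled cohort tibble.
#' @return The rule base with `support` and `confidence` columns refreshed
#'   from `cohort`.
#' @export
add_rule_stats <- function(rb, cohort) {
  stats <- purrr::map(seq_len(nrow(rb$rules)), function(i)
    compute_support_confidence(rb$rules[i, ], cohort, rb$schema))
  stats <- dplyr::bind_rows(stats)
  rb$rules$support <- stats$support
  rb$rules$confidence <- stats$confidence
  rb
}

#' Serialize a rule base to JSON / read it back
#'
#' The on-disk format keeps fixed field names so rule files interoperate
#' across deployments:
#' `{"schema": ..., "rules": [{"id": 1, "if": [{"factor": ..., "value": ...}],
#' "then": "delirium", "support": 1.73, "confidence": 100}], "provenance": {}}`.
#' Loading re-validates every rule against `schema`.
#'
#' @param rb A [rulebase()].
#' @param path JSON file path.
#' @return `write_rulebase()` returns `path` invisibly; `read_rulebase()`
#'   returns a validated [rulebase()].
#' @export
write_rulebase <- function(rb, path) {
  obj <- list(
    schema = schema_to_list(rb$schema),
    rules = purrr::map(seq_len(nrow(rb$rules)), function(i) {
      r <- rb$rules[i, ]
      cond <- r$conditions[[1]]
      list(
        id = r$rule_id,
        "if" = purrr::map(seq_len(nrow(cond)), function(j)
          list(factor = cond$factor[j], value = cond$value[j])),
        then = r$decision,
        support = if (is.na(r$support)) NULL else r$support,
        confidence = if (is.na(r$confidence)) NULL else r$confidence
      )
    }),
    provenance = rb$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_rulebase
#' @param schema Schema to validate against; by default the schema embedded
#'   in the JSON file is used.
#' @export
read_rulebase <- function(path, schema = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(schema)) {
    if (is.null(obj$schema)) stop("rule-base JSON has no schema and none was supplied",
                                  call. = FALSE)
    schema <- schema_from_list(obj$schema)
  }
  ids <- purrr::map_int(obj$rules, function(r) as.integer(r$id))
  if (anyDuplicated(ids)) {
    stop("duplicate rule_id in rule-base JSON: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rules <- purrr::map(obj$rules, function(r) {
    rule(
      rule_id = as.integer(r$id),
      conditions = tibble::tibble(
        factor = purrr::map_chr(r[["if"]], "factor"),
        value = purrr::map_chr(r[["if"]], "value")
      ),
      decision = r$then,
      support = if (is.null(r$support)) NA_real_ else as.numeric(r$support),
      confidence = if (is.null(r$confidence)) NA_real_ else as.numeric(r$confidence)
    )
  })
  prov <- obj$provenance %||% list()
  rulebase(dplyr::bind_rows(rules), schema, provenance = prov)
}
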