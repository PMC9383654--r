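#' Reasoning-engine configuration
#'
#' Holds the tunable constants of the knowledge-based reasoning step.
#' The shipped risk-tertile cut-offs are the 33.3rd and 66.7th percentiles
#' of the deployed delirium-rule supports (1.73% and 3.47%); deployments
#' re-inducing rules on their own cohorts may recompute them.
#'
#' @param tau_low Lower support cut-off (percent): delirium risk is `low`
#'   strictly below it. Default 1.73.
#' @param tau_high Upper support cut-off (percent): risk is `high` strictly
#'   above it; `[tau_low, tau_high]` is `medium` (closed interval). Default
#'   3.47.
#' @param min_matching_degree Minimum best matching degree (percent) for a
#'   prediction to be issued; below it [select_best_rule()] signals no
#'   match. Default 0: a partial match always yields an answer.
#' @param alarm_channels Channels an alarm event is routed to; subset of
#'   `"screen"`, `"vibration"`, `"sound"`. Default screen + vibration.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(tau_low = 1.73, tau_high = 3.47,
                          min_matching_degree = 0,
                          alarm_channels = c("screen", "vibration")) {
  if (!(tau_low > 0 && tau_low < tau_high && tau_high < 100)) {
    stop("need 0 < tau_low < tau_high < 100", call. = FALSE)
  }
  if (min_matching_degree < 0 || min_matching_degree > 100) {
    stop("min_matching_degree must lie in [0, 100]", call. = FALSE)
  }
  bad <- setdiff(alarm_channels, c("screen", "vibration", "sound"))
  if (length(bad)) stop("unknown alarm channel(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(tau_low = tau_low, tau_high = tau_high,
                 min_matching_degree = min_matching_degree,
                 alarm_channels = alarm_channels),
            class = "engine_config")
}

#' Matching degree between a rule and a patient record
#'
#' The percentage of the rule's conditions the record satisfies. A missing
#' value never satisfies a condition: the entry form collects only a subset
#' of the algorithm's factors, and an unanswered factor must not be taken
#' as a match.
#'
#' @param rule A one-row rule tibble ([rule()] or a rule-base row).
#' @param record A one-row cohort tibble or named list of factor values.
#' @return Percentage in `[0, 100]`.
#' @export
matching_degree <- function(rule, record) {
  if (!is.data.frame(record)) record <- tibble::as_tibble(as.list(record))
  cond <- rule$conditions[[1]]
  sat <- purrr::map_lgl(seq_len(nrow(cond)), function(j) {
    f <- cond$factor[j]
    if (!f %in% names(record)) return(FALSE)
    v <- record[[f]][1]
    !is.na(v) && v == cond$value[j]
  })
  100 * mean(sat)
}

# matching degree of every rule in the base against one record
matching_degrees <- function(rb, record) {
  purrr::map_dbl(seq_len(nrow(rb$rules)), function(i)
    matching_degree(rb$rules[i, ], record))
}

# argmax over matching degree, tie-broken by support*confidence then rule_id
best_rule_index <- function(rb, degrees) {
  cand <- which(degrees == max(degrees))
  if (length(cand) > 1) {
    prod <- rb$rules$support[cand] * rb$rules$confidence[cand]
    cand <- cand[prod == max(prod)]
  }
  cand[which.min(rb$rules$rule_id[cand])]
}

#' Select the best-matching rule for a record
#'
#' The rule with the highest matching degree wins; when two or more rules
#' tie, the one with the highest support x confidence product wins;
#' residual ties go to the lowest rule id (deterministic). When the best
#' matching degree falls below `config$min_matching_degree` no rule is
#' returned.
#'
#' @param rb A non-empty [rulebase()] with support/confidence filled in.
#' @param record A one-row cohort tibble or named list.
#' @param config An [engine_config()].
#' @return A one-row tibble: the winning rule with its `matching_degree`
#'   appended; a zero-row tibble when nothing reaches the threshold.
#' @export
select_best_rule <- function(rb, record, config = engine_config()) {
  if (nrow(rb$rules) == 0L) stop("empty rule base", call. = FALSE)
  deg <- matching_degrees(rb, record)
  if (max(deg) < config$min_matching_degree) {
    return(dplyr::mutate(rb$rules[0, ], matching_degree = numeric()))
  }
  best <- best_rule_index(rb, deg)
  dplyr::mutate(rb$rules[best, ], matching_degree = deg[best])
}

#' Stratify delirium risk from a rule's support
#'
#' Risk tertiles on the support of the matched delirium rule: `low` when
#' support < `tau_low`, `medium` on the closed interval
#' `[tau_low, tau_high]`, `high` above `tau_high`. The three levels
#' partition `[0, 100]`: every support value maps to exactly one level.
#'
#' @param support Numeric vector of rule supports (percent).
#' @param config An [engine_config()].
#' @return Character vector: `"low"`, `"medium"` or `"high"`.
#' @export
stratify_risk <- function(support, config = engine_config()) {
  stopifnot(all(support >= 0 & support <= 100))
  dplyr::case_when(
    support < config$tau_low ~ "low",
    support <= config$tau_high ~ "medium",
    TRUE ~ "high"
  )
}

#' Predict delirium risk for patient records
#'
#' The engine's end-to-end inference: for each record, select the best
#' rule (matching degree, then support x confidence, then rule id), take
#' its decision, and — when the decision is delirium — stratify risk by
#' the rule's support and raise the alarm flag. For a non-delirium
#' decision the risk level is `"none"` and no alarm is raised.
#'
#' @param records A cohort tibble (one row per patient; a `patient_id`
#'   column is carried through).
#' @param rb A [rulebase()] with support/confidence filled in.
#' @param config An [engine_config()].
#' @param audit_log Optional path to a JSON-lines audit file; each
#'   prediction is appended as one JSON object (timestamp, pseudonym,
#'   result, alarm channels).
#' @return A tibble with one row per record: `patient_id`, `best_rule_id`,
#'   `matching_degree`, `risk_percent` (the matched rule's support),
#'   `risk_level` (`low`/`medium`/`high`/`none`), `predicted_class`,
#'   `alarm`.
#' @export
predict_delirium <- function(records, rb, config = engine_config(),
                             audit_log = NULL) {
  if (nrow(rb$rules) == 0L) stop("empty rule base", call. = FALSE)
  positive <- rb$schema$target_levels[1]
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    best <- select_best_rule(rb, rec, config)
    pid <- if ("patient_id" %in% names(rec)) rec$patient_id else NA_character_
    if (nrow(best) == 0L) {
      return(tibble::tibble(
        patient_id = pid, best_rule_id = NA_integer_,
        matching_degree = NA_real_, risk_percent = NA_real_,
        risk_level = "none", predicted_class = NA_character_, alarm = FALSE
      ))
    }
    is_pos <- best$decision == positive
    tibble::tibble(
      patient_id = pid,
      best_rule_id = best$rule_id,
      matching_degree = best$matching_degree,
      risk_percent = best$support,
      risk_level = if (is_pos) stratify_risk(best$support, config) else "none",
      predicted_class = best$decision,
      alarm = is_pos
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(audit_log)) {
    con <- file(audit_log, open = "a")
    on.exit(close(con))
    for (i in seq_len(nrow(out))) {
      entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                 as.list(out[i, ]),
                 list(alarm_channels = if (out$alarm[i]) config$alarm_channels else character()))
      writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, null = "null"), con)
    }
  }
  out
}
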