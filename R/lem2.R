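#' Induce a rule base with the LEM2 local-covering algorithm
#'
#' LEM2 (Learning from Examples Module 2) is a rough-set rule learner. For
#' each target class it computes the class's approximation (by default the
#' lower approximation: records whose indiscernibility class lies entirely
#' inside the class, so the induced rules are *certain*) and then greedily
#' builds a local covering: condition sets that are consistent (cover only
#' approximation records), minimal (dropping any condition breaks
#' consistency) and jointly complete (their coverages union to the
#' approximation).
#'
#' Inner-loop ties when choosing the next attribute-value pair are broken
#' by (1) maximum relevance (records covered inside the current goal),
#' (2) minimum total coverage, (3) schema factor order then allowed-value
#' order. This fixed order makes induction deterministic: identical cohort
#' and configuration always yield an identical rule base.
#'
#' @param cohort Labelled cohort tibble; at least one record per class
#'   present is expected (a single-class cohort yields rules for that class
#'   only, with a warning). A factor column that is entirely missing is
#'   ignored with a warning.
#' @param schema The governing [rf_schema()].
#' @param target_order Classes to cover, in order. Default the schema's
#'   target levels (positive class first).
#' @param min_support_pct Drop induced rules with support below this
#'   percentage (default 0: keep all, preserving completeness).
#' @param consistency `"lower_approximation"` (certain rules, default) or
#'   `"upper_approximation"` (possible rules) for inconsistent data.
#' @return A [rulebase()] with support/confidence computed over `cohort`
#'   and provenance recording the induction parameters.
#' @export
lem2_induce <- function(cohort, schema,
                        target_order = schema$target_levels,
                        min_support_pct = 0,
                        consistency = c("lower_approximation", "upper_approximation")) {
  consistency <- match.arg(consistency)
  stopifnot(min_support_pct >= 0, min_support_pct <= 100)
  assert_valid_cohort(cohort, schema)
  lab <- cohort[[schema$target_name]]
  if (is.null(lab) || anyNA(lab)) stop("LEM2 needs a fully labelled cohort", call. = FALSE)

  fac <- intersect(schema_factor_names(schema), names(cohort))
  all_missing <- fac[purrr::map_lgl(fac, function(f) all(is.na(cohort[[f]])))]
  if (length(all_missing)) {
    warning("ignoring all-missing factor(s): ", paste(all_missing, collapse = ", "),
            call. = FALSE)
    fac <- setdiff(fac, all_missing)
  }
  X <- as.matrix(as.data.frame(lapply(cohort[fac], as.character)))
  colnames(X) <- fac
  n <- nrow(X)

  present <- intersect(target_order, unique(lab))
  if (length(present) < length(intersect(target_order, schema$target_levels))) {
    warning("cohort contains a single class; rules induced for ",
            paste(present, collapse = ", "), " only", call. = FALSE)
  }

  # indiscernibility classes over the full attribute vector (NA as a value)
  key <- apply(X, 1, paste, collapse = "\r")
  elem <- split(seq_len(n), key)

  approx_of <- function(class) {
    idx <- unlist(purrr::keep(elem, function(ix) {
      if (consistency == "lower_approximation") all(lab[ix] == class)
      else any(lab[ix] == class)
    }), use.names = FALSE)
    sort(idx)
  }

  # pre-compute [(a,v)] cover sets for all observed pairs, in deterministic order
  pair_tbl <- dplyr::bind_rows(purrr::map(fac, function(f) {
    vals <- intersect(allowed_values(schema, f), unique(stats::na.omit(X[, f])))
    tibble::tibble(factor = f, value = vals)
  }))
  pair_cover <- purrr::map(seq_len(nrow(pair_tbl)), function(i) {
    col <- X[, pair_tbl$factor[i]]
    which(!is.na(col) & col == pair_tbl$value[i])
  })

  covering_for <- function(B) {
    rules <- list()
    covered <- integer()
    G <- B
    while (length(G) > 0) {
      T_idx <- integer()        # indices into pair_tbl
      T_cover <- seq_len(n)
      repeat {
        used_factors <- pair_tbl$factor[T_idx]
        rel <- purrr::map_int(seq_len(nrow(pair_tbl)), function(i) {
          if (pair_tbl$factor[i] %in% used_factors) return(-1L)
          length(intersect(pair_cover[[i]], G))
        })
        if (max(rel) <= 0L) break  # cannot refine further (shouldn't occur on G != empty)
        cand <- which(rel == max(rel))
        if (length(cand) > 1) {
          tot <- lengths(pair_cover[cand])
          cand <- cand[tot == min(tot)]
        }
        t <- cand[1]  # pair_tbl is already in schema factor/value order
        T_idx <- c(T_idx, t)
        T_cover <- intersect(T_cover, pair_cover[[t]])
        G <- intersect(G, pair_cover[[t]])
        if (all(T_cover %in% B)) break
      }
      if (!all(T_cover %in% B)) {
        # data too inconsistent to describe the remaining goal; give up on it
        break
      }
      # minimality: drop conditions whose removal keeps the rule consistent
      for (t in T_idx) {
        if (length(T_idx) == 1L) break
        rest <- setdiff(T_idx, t)
        rest_cover <- Reduce(intersect, pair_cover[rest], seq_len(n))
        if (all(rest_cover %in% B)) {
          T_idx <- rest
          T_cover <- rest_cover
        }
      }
      rules[[length(rules) + 1L]] <- T_idx
      covered <- union(covered, T_cover)
      G <- setdiff(B, covered)
    }
    # completeness tidy-up: drop rules redundant for covering B
    if (length(rules) > 1) {
      keep <- rep(TRUE, length(rules))
      for (i in seq_along(rules)) {
        others <- which(keep & seq_along(rules) != i)
        if (length(others) == 0) next
        cov_others <- sort(unique(unlist(purrr::map(rules[others], function(T_idx)
          Reduce(intersect, pair_cover[T_idx], seq_len(n))))))
        if (all(B %in% cov_others)) keep[i] <- FALSE
      }
      rules <- rules[keep]
    }
    rules
  }

  out <- list()
  next_id <- 1L
  for (cls in present) {
    B <- approx_of(cls)
    if (length(B) == 0) next
    for (T_idx in covering_for(B)) {
      out[[length(out) + 1L]] <- rule(
        rule_id = next_id,
        conditions = pair_tbl[T_idx, ],
        decision = cls
      )
      next_id <- next_id + 1L
    }
  }
  if (length(out) == 0L) stop("LEM2 induced no rules (empty approximations)", call. = FALSE)

  rb <- rulebase(dplyr::bind_rows(out), schema,
                 provenance = list(
                   algorithm = "LEM2",
                   consistency_handling = consistency,
                   min_support_pct = min_support_pct,
                   support_basis = "training cohort",
                   n_records = n
                 ))
  rb <- add_rule_stats(rb, cohort)
  if (min_support_pct > 0) {
    rb$rules <- rb$rules[rb$rules$support >= min_support_pct, , drop = FALSE]
    if (nrow(rb$rules) == 0L) stop("min_support_pct filtered out every rule", call. = FALSE)
  }
  rb
}

#' Classify records with a rule base
#'
#' Strict mode prefers rules the record matches fully (matching degree
#' 100%), breaking ties by highest support x confidence, then lowest
#' rule id; a record with no full match falls back to partial mode.
#' Partial mode takes the decision of [select_best_rule()]'s winner
#' (highest matching degree, same tie-breaks), so an answer is always
#' produced.
#'
#' @param rb A [rulebase()] with support/confidence filled in.
#' @param records A cohort tibble (labels, if present, are ignored).
#' @param mode `"strict"` or `"partial"`.
#' @param config An [engine_config()] (used by the partial path).
#' @return Character vector of predicted classes, one per record.
#' @export
classify <- function(rb, records, mode = c("strict", "partial"),
                     config = engine_config()) {
  mode <- match.arg(mode)
  if (nrow(rb$rules) == 0L) stop("empty rule base", call. = FALSE)
  purrr::map_chr(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    deg <- matching_degrees(rb, rec)
    cand <- if (mode == "strict") which(deg == 100) else integer()
    if (length(cand) == 0L) {
      best <- best_rule_index(rb, deg)
    } else {
      prod <- rb$rules$support[cand] * rb$rules$confidence[cand]
      cand <- cand[prod == max(prod)]
      best <- cand[which.min(rb$rules$rule_id[cand])]
    }
    rb$rules$decision[best]
  })
}
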