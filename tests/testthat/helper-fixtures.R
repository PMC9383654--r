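# Shared fixtures and independent oracles used across test files.

# A tiny all-binary schema with k factors named f1..fk.
toy_schema <- function(k = 3) {
  rf_schema(tibble::tibble(factor = paste0("f", seq_len(k)), kind = "binary"))
}

# Build a labelled toy cohort from compact strings: "110" -> f1=yes f2=yes f3=no.
toy_cohort <- function(patterns, labels, schema = toy_schema(nchar(patterns[1]))) {
  k <- nrow(schema$factors)
  vals <- purrr::map(seq_len(k), function(j) {
    ifelse(substr(patterns, j, j) == "1", "yes", "no")
  })
  names(vals) <- schema$factors$factor
  d <- tibble::as_tibble(vals)
  d[[schema$target_name]] <- labels
  d
}

# Independent brute-force support/confidence (plain loops, no dplyr).
oracle_support_confidence <- function(cond, decision, cohort, target = "label") {
  n <- nrow(cohort)
  match_cnt <- 0L; hit_cnt <- 0L
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in seq_len(nrow(cond))) {
      v <- cohort[[cond$factor[j]]][i]
      if (is.na(v) || v != cond$value[j]) { ok <- FALSE; break }
    }
    if (ok) {
      match_cnt <- match_cnt + 1L
      if (!is.na(cohort[[target]][i]) && cohort[[target]][i] == decision) {
        hit_cnt <- hit_cnt + 1L
      }
    }
  }
  c(support = 100 * hit_cnt / n,
    confidence = if (match_cnt > 0) 100 * hit_cnt / match_cnt else 0)
}

# Exhaustive argmax oracle for best-rule selection: max matching degree,
# then max support*confidence, then lowest rule_id.
oracle_best_rule <- function(rb, record) {
  deg <- vapply(seq_len(nrow(rb$rules)), function(i)
    matching_degree(rb$rules[i, ], record), numeric(1))
  best <- NULL
  for (i in seq_len(nrow(rb$rules))) {
    key <- c(deg[i], rb$rules$support[i] * rb$rules$confidence[i], -rb$rules$rule_id[i])
    if (is.null(best) ||
        key[1] > best$key[1] ||
        (key[1] == best$key[1] && key[2] > best$key[2]) ||
        (key[1] == best$key[1] && key[2] == best$key[2] && key[3] > best$key[3])) {
      best <- list(i = i, key = key)
    }
  }
  best$i
}

# Random rule base + record pairs for property tests.
random_rulebase <- function(schema, n_rules, rng_support = TRUE) {
  fac <- schema$factors$factor
  rules <- purrr::map(seq_len(n_rules), function(i) {
    nc <- sample(1:min(3, length(fac)), 1)
    fs <- sample(fac, nc)
    rule(i, stats::setNames(sample(c("no", "yes"), nc, replace = TRUE), fs),
         sample(c("delirium", "non-delirium"), 1),
         support = if (rng_support) round(stats::runif(1, 0, 20), 2) else NA,
         confidence = if (rng_support) round(stats::runif(1, 20, 100), 2) else NA)
  })
  rulebase(dplyr::bind_rows(rules), schema)
}

random_record <- function(schema, p_missing = 0.2) {
  fac <- schema$factors$factor
  v <- sample(c("no", "yes"), length(fac), replace = TRUE)
  v[stats::runif(length(fac)) < p_missing] <- NA
  tibble::as_tibble(as.list(stats::setNames(v, fac)))
}

# Direct 2^n enumeration of the signed-rank null (independent of the
# package's dynamic-programming implementation).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  n <- length(d)
  stats <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    s <- 0
    for (i in seq_len(n)) if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0) s <- s + r[i]
    stats[mask + 1] <- s
  }
  mu <- sum(r) / 2
  mean(abs(stats - mu) >= abs(w - mu) - 1e-9)
}

# Independent rough-set oracles (plain loops over elementary sets and
# condition subsets; no shared code with the induction path).

oracle_approx <- function(co, fac, class, lower = TRUE, target = "label") {
  key <- apply(as.matrix(as.data.frame(co[fac])), 1, paste, collapse = "|")
  which(vapply(seq_len(nrow(co)), function(i) {
    labs <- co[[target]][key == key[i]]
    if (lower) all(labs == class) else any(labs == class)
  }, logical(1)))
}

cover_of <- function(cond, co) which(delirisk:::rule_matches(cond, co))

# Verifies by exhaustive subset enumeration that the rules of `class` in
# `rb` form a local covering of its lower approximation: consistent,
# minimal, and jointly complete.
check_local_covering <- function(rb, co, class, fac) {
  B <- oracle_approx(co, fac, class)
  rules <- rb$rules[rb$rules$decision == class, ]
  covered <- integer()
  for (i in seq_len(nrow(rules))) {
    cond <- rules$conditions[[i]]
    cov <- cover_of(cond, co)
    testthat::expect_true(all(cov %in% B),
                          label = "rule consistency (cover inside approximation)")
    # minimality, exhaustively: no proper subset of the conditions is consistent
    if (nrow(cond) > 1) {
      for (m in 1:(2^nrow(cond) - 2)) {
        keep <- which(bitwAnd(m, bitwShiftL(1L, seq_len(nrow(cond)) - 1L)) != 0)
        sub_cov <- cover_of(cond[keep, ], co)
        testthat::expect_false(all(sub_cov %in% B),
                               label = "minimality (every proper condition subset is inconsistent)")
      }
    }
    covered <- union(covered, cov)
  }
  testthat::expect_setequal(covered, B)  # completeness
}

# A random small labelled toy table for exhaustive LEM2 checks.
random_toy_table <- function(n_max = 10, k_max = 4) {
  k <- sample(2:k_max, 1)
  n <- sample(4:n_max, 1)
  s <- toy_schema(k)
  pat <- vapply(seq_len(n), function(i)
    paste(sample(0:1, k, replace = TRUE), collapse = ""), character(1))
  lab <- sample(c("delirium", "non-delirium"), n, replace = TRUE)
  # ensure both classes appear
  lab[1] <- "delirium"; lab[2] <- "non-delirium"
  list(schema = s, cohort = toy_cohort(pat, lab, s))
}
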