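#' Construct a risk-factor schema
#'
#' A schema declares the risk factors a cohort may record (name, kind and
#' allowed values per factor) plus the decision attribute. All cohort I/O,
#' rule validation and inference are carried out against a schema.
#'
#' @param factors A data frame with columns `factor` (unique, non-empty
#'   names), `kind` (`"binary"` or `"categorical"`) and `values` (list
#'   column of allowed values; binary factors default to `c("no", "yes")`).
#' @param target_name Name of the decision attribute column. Default
#'   `"label"`.
#' @param target_levels Allowed decision values; the first level is the
#'   positive (alarm-raising) class. Default `c("delirium", "non-delirium")`.
#'
#' @return An object of class `rf_schema`.
#' @seealso [default_schema()] for the shipped 24-factor schema.
#' @export
rf_schema <- function(factors,
                      target_name = "label",
                      target_levels = c("delirium", "non-delirium")) {
  factors <- tibble::as_tibble(factors)
  if (!all(c("factor", "kind") %in% names(factors))) {
    stop("`factors` must have columns `factor` and `kind`", call. = FALSE)
  }
  if (!"values" %in% names(factors)) {
    factors$values <- vector("list", nrow(factors))
  }
  factors$values <- purrr::map2(factors$values, factors$kind, function(v, k) {
    if (is.null(v)) {
      if (k != "binary") stop("categorical factors need explicit `values`", call. = FALSE)
      c("no", "yes")
    } else {
      as.character(v)
    }
  })
  if (anyDuplicated(factors$factor) || any(!nzchar(factors$factor))) {
    stop("factor names must be unique and non-empty", call. = FALSE)
  }
  if (!all(factors$kind %in% c("binary", "categorical"))) {
    stop("factor kind must be 'binary' or 'categorical'", call. = FALSE)
  }
  n_vals <- lengths(factors$values)
  if (any(factors$kind == "binary" & n_vals != 2L)) {
    stop("binary factors must have exactly 2 allowed values", call. = FALSE)
  }
  if (any(n_vals < 2L)) {
    stop("every factor needs at least 2 allowed values", call. = FALSE)
  }
  if (length(target_levels) < 2L) stop("need at least 2 target levels", call. = FALSE)
  structure(
    list(
      factors = factors[, c("factor", "kind", "values")],
      target_name = target_name,
      target_levels = as.character(target_levels)
    ),
    class = "rf_schema"
  )
}

#' @export
print.rf_schema <- function(x, ...) {
  cat("<rf_schema> ", nrow(x$factors), " factors; target `", x$target_name,
      "` in {", paste(x$target_levels, collapse = ", "), "}\n", sep = "")
  print(x$factors, n = 6)
  invisible(x)
}

#' The default 24-factor delirium risk schema
#'
#' Ships the 24 binary risk factors the prediction engine expects. Factors
#' the source application names in its entry form (age at least 65,
#' disease severity, abnormal blood urea nitrogen, dehydration,
#' water-electrolyte imbalance, nutritional imbalance, hypoxia, infection,
#' sleep disorder, surgery with general anaesthesia, oedema, number of
#' comorbidities, pain, pain-medicine use) carry descriptive names; the
#' remainder are placeholders (`factor_15` .. `factor_24`) that deployments
#' replace with their own factor list via [rf_schema()].
#'
#' @return An `rf_schema` with exactly 24 binary factors.
#' @export
default_schema <- function() {
  named <- c(
    "age_65_or_over", "disease_severity", "abnormal_bun", "dehydration",
    "water_electrolyte_imbalance", "nutritional_imbalance", "hypoxia",
    "infection", "sleep_disorder", "general_anaesthesia_surgery", "oedema",
    "multiple_comorbidities", "pain", "pain_medicine_use"
  )
  nm <- c(named, sprintf("factor_%02d", seq(length(named) + 1L, 24L)))
  rf_schema(tibble::tibble(factor = nm, kind = "binary"))
}

schema_factor_names <- function(schema) schema$factors$factor

allowed_values <- function(schema, factor) {
  i <- match(factor, schema$factors$factor)
  if (is.na(i)) stop("unknown factor: ", factor, call. = FALSE)
  schema$factors$values[[i]]
}

#' Validate a single patient record against a schema
#'
#' Violations are returned, never raised: an empty result means the record
#' is legal. A missing value (`NA`) is always legal — the entry form
#' collects only a subset of the algorithm's factors, and inference treats
#' missing as never matching a rule condition.
#'
#' @param record A named list or one-row data frame of factor values
#'   (and optionally the target column and `patient_id`).
#' @param schema An [rf_schema()].
#'
#' @return A tibble with columns `field` and `problem`, zero rows when the
#'   record is valid. Field order of the input does not affect the result.
#' @export
validate_record <- function(record, schema) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  nm <- names(record)
  keep <- setdiff(nm, c("patient_id", schema$target_name))
  known <- schema_factor_names(schema)
  out <- list()
  for (f in sort(setdiff(keep, known))) {
    out[[length(out) + 1L]] <- c(f, "unknown factor")
  }
  for (f in intersect(known, keep)) {
    v <- record[[f]]
    if (length(v) != 1L) {
      out[[length(out) + 1L]] <- c(f, "value must be length 1")
    } else if (!is.na(v) && !as.character(v) %in% allowed_values(schema, f)) {
      out[[length(out) + 1L]] <- c(f, paste0("illegal value '", v, "'"))
    }
  }
  if (schema$target_name %in% nm) {
    lab <- record[[schema$target_name]]
    if (!is.na(lab) && !as.character(lab) %in% schema$target_levels) {
      out[[length(out) + 1L]] <- c(schema$target_name, paste0("illegal label '", lab, "'"))
    }
  }
  if (length(out) == 0L) {
    tibble::tibble(field = character(), problem = character())
  } else {
    m <- do.call(rbind, out)
    tibble::tibble(field = m[, 1], problem = m[, 2])
  }
}

#' Validate a whole cohort
#'
#' @param data A cohort tibble (one row per patient; columns are factor
#'   names, optionally `patient_id` and the target column).
#' @param schema An [rf_schema()].
#' @return A tibble `row`, `field`, `problem`; zero rows when clean.
#' @export
validate_cohort <- function(data, schema) {
  if (nrow(data) < 1L) stop("cohort must contain at least one record", call. = FALSE)
  unknown <- sort(setdiff(names(data), c("patient_id", schema$target_name,
                                         schema_factor_names(schema))))
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    v <- validate_record(data[i, , drop = FALSE], schema)
    v <- v[!v$field %in% unknown, , drop = FALSE]  # report unknown columns once
    if (nrow(v)) dplyr::mutate(v, row = i, .before = 1) else NULL
  })
  head_part <- if (length(unknown)) {
    tibble::tibble(row = NA_integer_, field = unknown, problem = "unknown factor")
  } else NULL
  dplyr::bind_rows(head_part, rows)
}

assert_valid_cohort <- function(data, schema) {
  v <- validate_cohort(data, schema)
  if (nrow(v)) {
    bad <- v[1, ]
    stop("invalid cohort: ", bad$problem, " (column `", bad$field, "`",
         if (!is.na(bad$row)) paste0(", row ", bad$row), ")",
         if (nrow(v) > 1) paste0(" and ", nrow(v) - 1, " more violation(s)"),
         call. = FALSE)
  }
  invisible(data)
}

#' Read a cohort from CSV or JSON
#'
#' CSV: comma-separated, UTF-8, header row of factor names (plus optional
#' `patient_id` and label columns); an empty cell is a missing value. JSON:
#' an object with `"schema"` and `"records"` entries as written by
#' [write_cohort()].
#'
#' @param path File path.
#' @param schema The governing [rf_schema()].
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, schema, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  data <- if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    na = "", progress = FALSE)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(obj$records)) stop("JSON cohort lacks a `records` array", call. = FALSE)
    recs <- purrr::map(obj$records, function(r) {
      vals <- purrr::map(r$values, function(v) if (is.null(v)) NA_character_ else as.character(v))
      out <- c(list(patient_id = r$patient_id %||% NA_character_), vals)
      if (!is.null(r$label)) out[[schema$target_name]] <- as.character(r$label)
      tibble::as_tibble(out)
    })
    dplyr::bind_rows(recs)
  }
  # normalize column order: patient_id, factors present, label
  ord <- intersect(c("patient_id", schema_factor_names(schema), schema$target_name),
                   names(data))
  data <- data[, c(ord, setdiff(names(data), ord)), drop = FALSE]
  assert_valid_cohort(data, schema)
  tibble::as_tibble(data)
}

#' Write a cohort to CSV or JSON
#'
#' @inheritParams read_cohort
#' @param data The cohort tibble.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, schema, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  assert_valid_cohort(data, schema)
  if (format == "csv") {
    readr::write_csv(data, path, na = "")
  } else {
    fac <- intersect(schema_factor_names(schema), names(data))
    records <- purrr::map(seq_len(nrow(data)), function(i) {
      r <- data[i, ]
      rec <- list(
        patient_id = if ("patient_id" %in% names(r)) r$patient_id else NULL,
        values = purrr::map(as.list(r[fac]), function(v) if (is.na(v)) NULL else v)
      )
      if (schema$target_name %in% names(r) && !is.na(r[[schema$target_name]])) {
        rec$label <- r[[schema$target_name]]
      }
      rec
    })
    jsonlite::write_json(list(schema = schema_to_list(schema), records = records),
                         path, auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}

schema_to_list <- function(schema) {
  list(
    factors = purrr::pmap(schema$factors, function(factor, kind, values) {
      list(name = factor, kind = kind, values = as.list(values))
    }),
    target_name = schema$target_name,
    target_levels = as.list(schema$target_levels)
  )
}

schema_from_list <- function(obj) {
  rf_schema(
    tibble::tibble(
      factor = purrr::map_chr(obj$factors, "name"),
      kind = purrr::map_chr(obj$factors, "kind"),
      values = purrr::map(obj$factors, function(f) unlist(f$values))
    ),
    target_name = obj$target_name %||% "label",
    target_levels = unlist(obj$target_levels %||% list("delirium", "non-delirium"))
  )
}

#' Read or write a schema as JSON
#' @param path File path.
#' @return `read_schema()` returns an [rf_schema()]; `write_schema()`
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  schema_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' @rdname read_schema
#' @param schema An [rf_schema()].
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(schema_to_list(schema), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
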