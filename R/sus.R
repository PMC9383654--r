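#' Score System Usability Scale responses
#'
#' The SUS is a 10-item questionnaire on a 5-point Likert scale (1 = not
#' at all, 5 = strongly agree). Standard (Brooke) scoring — the default —
#' maps odd items to `value - 1` and even (negatively-worded) items to
#' `5 - value`, sums the contributions and multiplies by 2.5, giving a
#' score on `[0, 100]`; 68 or higher is conventionally above average.
#' `mode = "raw_sum"` instead multiplies the raw item sum by 2.5
#' (range `[25, 125]`), provided for transparency where a deployment
#' described its scoring that way; it cannot produce the 0-100 range and
#' is not the default.
#'
#' @param responses A data frame with 10 integer columns (items 1-10 in
#'   order; any names), one row per respondent — or a single numeric
#'   vector of length 10.
#' @param mode `"standard"` (default) or `"raw_sum"`.
#' @return A tibble with one row per respondent: `score` and
#'   `above_average` (`score >= 68`).
#' @export
sus_score <- function(responses, mode = c("standard", "raw_sum")) {
  mode <- match.arg(mode)
  if (is.numeric(responses) && is.null(dim(responses))) {
    responses <- as.data.frame(as.list(stats::setNames(responses,
                                                       paste0("item_", seq_along(responses)))))
  }
  m <- as.matrix(responses)
  if (ncol(m) != 10L) stop("SUS needs exactly 10 items, got ", ncol(m), call. = FALSE)
  if (!is.numeric(m) || anyNA(m) || any(m != round(m)) || any(m < 1 | m > 5)) {
    stop("every SUS item must be an integer in 1..5", call. = FALSE)
  }
  odd <- seq(1, 9, by = 2)
  even <- seq(2, 10, by = 2)
  score <- if (mode == "standard") {
    2.5 * (rowSums(m[, odd, drop = FALSE] - 1) + rowSums(5 - m[, even, drop = FALSE]))
  } else {
    2.5 * rowSums(m)
  }
  tibble::tibble(score = as.numeric(score), above_average = score >= 68)
}
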