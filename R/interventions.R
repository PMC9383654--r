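#' Shipped multi-component intervention catalogue
#'
#' The non-pharmacological preventive items the app offers, in three
#' components: orientation interventions, environmental interventions and
#' early avoidance of risk factors.
#'
#' @return A tibble with columns `category` (`orientation`,
#'   `environmental`, `risk_avoidance`) and `item`.
#' @export
intervention_catalogue <- function() {
  tibble::tribble(
    ~category, ~item,
    "orientation", "Use a clock or calendar for repeated orientation",
    "orientation", "Address the patient by name when providing care",
    "orientation", "Place familiar objects close to the patient",
    "orientation", "Encourage regular family visits",
    "orientation", "Detect abnormalities early",
    "orientation", "Encourage regular involvement in activities of daily living",
    "orientation", "Provide assistive devices for vision and hearing (eyeglasses, hearing aids)",
    "environmental", "Use indirect lighting and reduce ambient noise for an appropriate sleeping environment",
    "environmental", "Keep the same nurse in the same ward",
    "environmental", "Distinguish day and night using window curtains or blinds",
    "environmental", "Encourage continuing hobbies (listening to music, playing games, hand-knitting)",
    "environmental", "Provide or read newspapers daily",
    "environmental", "Encourage meaningful conversations to stimulate memory and reasoning",
    "risk_avoidance", "Provide an appropriate amount of water and prevent dehydration",
    "risk_avoidance", "Manage pain pharmacologically and non-pharmacologically",
    "risk_avoidance", "Minimise the use of restraints",
    "risk_avoidance", "Active and passive range-of-motion exercises; encourage walking",
    "risk_avoidance", "Evaluate nutritional intake; provide non-oral feeding if necessary",
    "risk_avoidance", "Detect and treat infection early",
    "risk_avoidance", "Use anticholinergic drugs and opioids carefully; minimise unnecessary drugs",
    "risk_avoidance", "Monitor for hypoxia",
    "risk_avoidance", "Prevent constipation, falls and pressure ulcers"
  )
}

#' Build a preventive-intervention plan
#'
#' Issues the full three-component checklist to eligible patients. Under
#' the default `"preventive"` policy a plan is issued for high predicted
#' risk OR a positive delirium screen (prevention bias); under `"strict"`
#' only for high risk AND a positive screen. Ineligible patients get an
#' empty plan.
#'
#' @param risk_level One of `"low"`, `"medium"`, `"high"`, `"none"`.
#' @param scam_positive Logical: the S-CAM determination
#'   (`delirium_positive` from [assess_scam()]).
#' @param catalogue Item catalogue tibble (`category`, `item`); item texts
#'   must be unique. Default [intervention_catalogue()].
#' @param policy Eligibility policy, `"preventive"` (default) or
#'   `"strict"`.
#' @param patient_id Optional pseudonym carried into the plan.
#' @return A plan tibble: `patient_id`, `category`, `item`, `completed`
#'   (all `FALSE`), `timestamp` (all `NA`). Zero rows when ineligible.
#' @export
build_plan <- function(risk_level, scam_positive,
                       catalogue = intervention_catalogue(),
                       policy = c("preventive", "strict"),
                       patient_id = NA_character_) {
  policy <- match.arg(policy)
  if (!risk_level %in% c("low", "medium", "high", "none")) {
    stop("unknown risk level: ", risk_level, call. = FALSE)
  }
  stopifnot(is.logical(scam_positive), length(scam_positive) == 1L, !is.na(scam_positive))
  if (anyDuplicated(catalogue$item)) {
    stop("catalogue item texts must be unique", call. = FALSE)
  }
  bad_cat <- setdiff(unique(catalogue$category),
                     c("orientation", "environmental", "risk_avoidance"))
  if (length(bad_cat)) stop("unknown catalogue category: ",
                            paste(bad_cat, collapse = ", "), call. = FALSE)
  eligible <- if (policy == "strict") {
    risk_level == "high" && scam_positive
  } else {
    risk_level == "high" || scam_positive
  }
  items <- if (eligible) catalogue else catalogue[0, ]
  dplyr::mutate(tibble::as_tibble(items),
                patient_id = patient_id, .before = 1) |>
    dplyr::mutate(completed = FALSE, timestamp = as.POSIXct(NA))
}

#' Mark plan items as completed
#'
#' @param plan A plan tibble from [build_plan()].
#' @param items Character vector of item texts to mark.
#' @param timestamp Completion time recorded on the marked items.
#' @return The updated plan.
#' @export
mark_completed <- function(plan, items, timestamp = Sys.time()) {
  unknown <- setdiff(items, plan$item)
  if (length(unknown)) stop("item(s) not in plan: ", paste(unknown, collapse = "; "),
                            call. = FALSE)
  hit <- plan$item %in% items
  plan$completed[hit] <- TRUE
  plan$timestamp[hit] <- timestamp
  plan
}

#' Intervention performance rate
#'
#' Percentage of plan items marked completed, rounded half-up to one
#' decimal for display parity with the app.
#'
#' @param plan A non-empty plan tibble from [build_plan()].
#' @return Percentage in `[0, 100]` with one decimal.
#' @export
performance_rate <- function(plan) {
  if (nrow(plan) == 0L) stop("performance rate undefined for an empty plan", call. = FALSE)
  floor(1000 * sum(plan$completed) / nrow(plan) + 0.5) / 10
}
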