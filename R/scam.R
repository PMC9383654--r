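#' Short Confusion Assessment Method (S-CAM) determination
#'
#' Applies the four-step screening logic embedded in the app. Step 1 asks
#' two questions (acute onset; fluctuation of consciousness), Step 2 checks
#' inattention, Step 3 disorganized thinking, Step 4 the level of
#' consciousness (`normal`, `vigilant`, `lethargic`, `stuporous`,
#' `comatose`; any non-normal level counts as an abnormal — "YES" —
#' finding). Box 1 pools Steps 1-2, Box 2 pools Steps 3-4.
#'
#' The deployed determination is: delirium-positive iff Step 2 is YES, at
#' least one YES in Box 1, and at least one YES in Box 2. Since a Step-2
#' YES already puts a YES in Box 1, this reduces to
#' `step2 AND (step3 OR step4 != normal)`. The classic CAM instead requires
#' feature 1 (acute onset/fluctuation) AND feature 2 AND (feature 3 OR
#' feature 4); set `standard_cam = TRUE` for that stricter variant.
#'
#' @param responses A data frame with one row per assessment and columns
#'   `step1_acute_onset`, `step1_fluctuation`, `step2_inattention`,
#'   `step3_disorganized_thinking` (each `"yes"`/`"no"` or logical) and
#'   `step4_consciousness` (one of the five levels). An optional `subtype`
#'   column (`hyperactive`/`hypoactive`/`mixed`, user-assessed, never
#'   computed) is carried through.
#' @param standard_cam Use the classic CAM positivity rule instead of the
#'   deployed one. Default `FALSE`.
#' @return The input tibble plus `box1_any_yes`, `box2_any_yes` and
#'   `delirium_positive`.
#' @export
assess_scam <- function(responses, standard_cam = FALSE) {
  responses <- tibble::as_tibble(responses)
  need <- c("step1_acute_onset", "step1_fluctuation", "step2_inattention",
            "step3_disorganized_thinking", "step4_consciousness")
  miss <- setdiff(need, names(responses))
  if (length(miss)) stop("missing S-CAM field(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  as_yes <- function(x, field) {
    if (is.logical(x)) {
      if (anyNA(x)) stop("S-CAM field `", field, "` has missing responses", call. = FALSE)
      return(x)
    }
    x <- tolower(as.character(x))
    if (anyNA(x) || !all(x %in% c("yes", "no"))) {
      stop("S-CAM field `", field, "` must be yes/no", call. = FALSE)
    }
    x == "yes"
  }
  s1a <- as_yes(responses$step1_acute_onset, "step1_acute_onset")
  s1f <- as_yes(responses$step1_fluctuation, "step1_fluctuation")
  s2 <- as_yes(responses$step2_inattention, "step2_inattention")
  s3 <- as_yes(responses$step3_disorganized_thinking, "step3_disorganized_thinking")
  s4 <- tolower(as.character(responses$step4_consciousness))
  levels <- c("normal", "vigilant", "lethargic", "stuporous", "comatose")
  if (anyNA(s4) || !all(s4 %in% levels)) {
    stop("step4_consciousness must be one of: ", paste(levels, collapse = ", "),
         call. = FALSE)
  }
  if ("subtype" %in% names(responses)) {
    st <- responses$subtype
    ok <- is.na(st) | st %in% c("hyperactive", "hypoactive", "mixed")
    if (!all(ok)) stop("subtype must be hyperactive, hypoactive or mixed", call. = FALSE)
  }
  box1 <- s1a | s1f | s2
  box2 <- s3 | (s4 != "normal")
  positive <- if (standard_cam) (s1a | s1f) & s2 & box2 else s2 & box1 & box2
  dplyr::mutate(responses,
                box1_any_yes = box1,
                box2_any_yes = box2,
                delirium_positive = positive)
}
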