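# Cause-of-death taxonomy for the neonatal VA validation pipeline.
#
# Ten assignable causes plus two terminal labels: "unexplained" (no case
# definition met) and "unclassifiable" (all three adjudicating reviewers
# disagreed). The terminal labels are outputs only; they are never valid as
# eligibility-flag keys or reviewer calls.

#' Neonatal cause-of-death taxonomy
#'
#' Returns the fixed cause taxonomy used throughout the package: ten
#' assignable causes (those a reviewer or the assignment hierarchy can
#' produce) and two terminal labels, `unexplained` (no case definition met)
#' and `unclassifiable` (adjudication failed because all three reviewers
#' disagreed).
#'
#' @return A tibble with columns `cause` (machine code), `display_name`, and
#'   `assignable` (logical; `FALSE` for the two terminal labels).
#' @examples
#' va_causes()
#' @export
va_causes <- function() {
  tibble(
    cause = c(
      "congenital_anomalies", "injuries", "birth_asphyxia", "tetanus",
      "sepsis", "meningitis", "pneumonia", "diarrhea",
      "prematurity_complications", "other_specific",
      "unexplained", "unclassifiable"
    ),
    display_name = c(
      "Congenital anomalies", "Injuries (not birth related)",
      "Birth asphyxia", "Tetanus", "Sepsis", "Meningitis", "Pneumonia",
      "Diarrhea", "Prematurity complications", "Other specific cause",
      "Unexplained neonatal death", "Unclassifiable"
    ),
    assignable = c(rep(TRUE, 10), FALSE, FALSE)
  )
}

#' Assignable cause codes
#'
#' The ten cause codes that reviewers and the assignment hierarchy can
#' produce (i.e. everything except the terminal labels).
#'
#' @return Character vector of cause codes.
#' @export
assignable_causes <- function() {
  tab <- va_causes()
  tab$cause[tab$assignable]
}

#' Severe-infection composite group
#'
#' The member causes of the severe-infection composite used for grouped
#' accuracy reporting, in fixed priority order (sepsis, meningitis,
#' pneumonia, diarrhea). The order also resolves which member label the
#' hierarchy returns when the composite "serious infection" slot fires.
#'
#' @return Character vector of the four member cause codes.
#' @export
severe_infection_causes <- function() {
  c("sepsis", "meningitis", "pneumonia", "diarrhea")
}

# Valid labels for final (adjudicated) diagnoses.
final_labels <- function() c(assignable_causes(), "unexplained", "unclassifiable")

# Causes a reviewer can call: everything assignable plus "unexplained"
# (a reviewer may find no case definition met); never "unclassifiable",
# which only adjudication can produce.
reviewable_causes <- function() c(assignable_causes(), "unexplained")

check_cause_codes <- function(x, allowed = assignable_causes(),
                              what = "cause") {
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown %s code(s): %s. Valid codes: %s.",
      what, paste(sQuote(bad), collapse = ", "),
      paste(allowed, collapse = ", ")
    ))
  }
  invisible(x)
}
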