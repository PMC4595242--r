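# Dual-reviewer + arbiter adjudication. Two blinded reviewers each call a
# cause; on disagreement a third senior reviewer arbitrates and the cause two
# of the three agree on is assigned. If all three differ the case is
# "unclassifiable".

#' Resolve reviewer disagreements case by case
#'
#' Vectorised adjudication rule: when the two primary reviewers agree, their
#' common call is final (`consensus`); when they disagree and the arbiter
#' sides with one of them, the arbiter's call is final
#' (`arbiter_agrees_r1`/`arbiter_agrees_r2`); when all three calls are
#' pairwise distinct the case is `unclassifiable`. The arbiter never
#' overrides both reviewers with a fourth cause.
#'
#' @param r1,r2 Character vectors of the two primary reviewers' cause codes.
#' @param arbiter Character vector of arbiter calls; must be `NA` exactly
#'   where `r1 == r2` (an arbiter call on a consensus case is ignored with a
#'   warning; a missing arbiter on a discrepant case is an error).
#' @return A tibble with columns `final_cause` and `resolution`.
#' @examples
#' resolve_cases(
#'   r1 = c("sepsis", "sepsis"),
#'   r2 = c("sepsis", "birth_asphyxia"),
#'   arbiter = c(NA, "birth_asphyxia")
#' )
#' @export
resolve_cases <- function(r1, r2, arbiter = NA_character_) {
  n <- length(r1)
  if (length(r2) != n) abort("`r1` and `r2` must have equal length.")
  arbiter <- rep_len(arbiter, n)
  if (any(is.na(r1)) || any(is.na(r2))) {
    abort("Primary reviewer calls `r1` and `r2` must not be missing.")
  }
  check_cause_codes(c(r1, r2), reviewable_causes(), what = "reviewer cause")
  check_cause_codes(arbiter, reviewable_causes(), what = "arbiter cause")

  agree <- r1 == r2
  if (any(agree & !is.na(arbiter))) {
    warn(sprintf(
      "Arbiter call supplied for %d consensus case(s); ignored.",
      sum(agree & !is.na(arbiter))
    ))
  }
  if (any(!agree & is.na(arbiter))) {
    abort(sprintf(
      "Arbiter call missing for %d discrepant case(s).",
      sum(!agree & is.na(arbiter))
    ))
  }

  final <- r1
  resolution <- rep("consensus", n)
  d1 <- !agree & !is.na(arbiter) & arbiter == r1
  d2 <- !agree & !is.na(arbiter) & arbiter == r2
  d0 <- !agree & !d1 & !d2
  final[d1] <- r1[d1]; resolution[d1] <- "arbiter_agrees_r1"
  final[d2] <- r2[d2]; resolution[d2] <- "arbiter_agrees_r2"
  final[d0] <- "unclassifiable"; resolution[d0] <- "unclassifiable"
  tibble(final_cause = final, resolution = resolution)
}

#' Adjudicate a reviewer-assignment table
#'
#' Takes a long table of reviewer calls (two `primary`-round calls from
#' distinct reviewers per case, plus an `arbiter`-round call exactly where
#' the primary calls disagree) and produces one final adjudicated diagnosis
#' per case via [resolve_cases()]. Primary calls are ordered by
#' `reviewer_id` so the result does not depend on row order.
#'
#' @param reviews Data frame with columns `case_id`, `reviewer_id`, `round`
#'   (`"primary"` or `"arbiter"`), `cause`.
#' @return A tibble with columns `case_id`, `final_cause`, `resolution`.
#' @export
adjudicate <- function(reviews) {
  check_data_frame(reviews, "reviews")
  check_columns(reviews, c("case_id", "reviewer_id", "round", "cause"),
                "reviews")
  bad_round <- setdiff(unique(reviews$round), c("primary", "arbiter"))
  if (length(bad_round) > 0) {
    abort(sprintf("Unknown review round(s): %s.",
                  paste(sQuote(bad_round), collapse = ", ")))
  }
  check_cause_codes(reviews$cause, reviewable_causes(), what = "reviewer cause")

  prim <- reviews[reviews$round == "primary", ]
  arb <- reviews[reviews$round == "arbiter", ]
  check_unique_ids(arb$case_id, "reviews (arbiter round)")

  counts <- table(prim$case_id)
  if (any(counts != 2)) {
    abort(sprintf(
      "Each case needs exactly two primary reviews; offending case_id(s): %s.",
      paste(head(names(counts)[counts != 2], 5), collapse = ", ")
    ))
  }
  dup_rev <- prim |>
    dplyr::count(.data$case_id, .data$reviewer_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_rev) > 0) {
    abort(sprintf(
      "Primary reviews must come from distinct reviewers; case_id(s): %s.",
      paste(head(dup_rev$case_id, 5), collapse = ", ")
    ))
  }

  wide <- prim |>
    dplyr::arrange(.data$case_id, .data$reviewer_id) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(r1 = .data$cause[1], r2 = .data$cause[2]) |>
    dplyr::left_join(
      dplyr::select(arb, "case_id", arbiter = "cause"),
      by = "case_id"
    )

  dplyr::bind_cols(
    dplyr::select(wide, "case_id"),
    resolve_cases(wide$r1, wide$r2, wide$arbiter)
  )
}

#' Summarise adjudication outcomes
#'
#' Consensus/discrepancy accounting over a set of adjudicated diagnoses:
#' how many cases the two primary reviewers agreed on, how many needed the
#' arbiter, and among those how many the arbiter settled versus how many
#' ended unclassifiable because all three reviewers differed.
#'
#' @param diagnoses Data frame with columns `case_id` and `resolution`
#'   (as produced by [adjudicate()]).
#' @return A one-row tibble: `n_reviewed`, `n_consensus`, `n_discrepant`,
#'   `n_arbiter_agrees_one`, `n_all_differ`, and `pct_consensus` (half-up,
#'   one decimal).
#' @examples
#' d <- adjudicate(tibble::tibble(
#'   case_id = c("a", "a", "b", "b", "b"),
#'   reviewer_id = c("R1", "R2", "R1", "R2", "R3"),
#'   round = c("primary", "primary", "primary", "primary", "arbiter"),
#'   cause = c("sepsis", "sepsis", "sepsis", "tetanus", "tetanus")
#' ))
#' summarize_adjudication(d)
#' @export
summarize_adjudication <- function(diagnoses) {
  check_data_frame(diagnoses, "diagnoses")
  check_columns(diagnoses, c("case_id", "resolution"), "diagnoses")
  if (nrow(diagnoses) == 0) abort("`diagnoses` must be non-empty.")
  check_unique_ids(diagnoses$case_id, "diagnoses")
  bad <- setdiff(
    unique(diagnoses$resolution),
    c("consensus", "arbiter_agrees_r1", "arbiter_agrees_r2", "unclassifiable")
  )
  if (length(bad) > 0) {
    abort(sprintf("Unknown resolution value(s): %s.",
                  paste(sQuote(bad), collapse = ", ")))
  }
  res <- diagnoses$resolution
  n <- length(res)
  n_cons <- sum(res == "consensus")
  n_arb <- sum(res %in% c("arbiter_agrees_r1", "arbiter_agrees_r2"))
  n_diff <- sum(res == "unclassifiable")
  tibble(
    n_reviewed = n,
    n_consensus = n_cons,
    n_discrepant = n_arb + n_diff,
    n_arbiter_agrees_one = n_arb,
    n_all_differ = n_diff,
    pct_consensus = round_half_up(100 * n_cons / n, 1)
  )
}
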