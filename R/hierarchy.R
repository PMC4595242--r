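# Age/gestation-stratified hierarchy for assigning the primary cause of a
# neonatal death. Within each of four strata (age at death < 3 vs >= 3
# completed days, gestation < 32 vs >= 32 weeks) causes are tried in a fixed
# order and the first one whose case definition is met becomes the primary
# cause. "Serious infection" is a composite slot that resolves to the
# highest-priority eligible member (sepsis > meningitis > pneumonia >
# diarrhea). If nothing fires the death is "unexplained".

#' The cause-assignment hierarchy
#'
#' The ordered candidate-cause lists for the four age/gestation strata.
#' Asphyxia carries an extra age condition (only assignable before day 7) in
#' the two strata for deaths at 3 or more completed days. The
#' `severe_infection` slot is a composite that expands to its member causes
#' in fixed priority order.
#'
#' @return A tibble with columns `stratum` (one of `lt3_lt32`, `ge3_lt32`,
#'   `lt3_ge32`, `ge3_ge32`), `rank`, `slot` (a cause code or
#'   `"severe_infection"`), and `age_lt_days` (`NA` or `7`, the strict upper
#'   age bound attached to that slot).
#' @export
hierarchy_table <- function() {
  strata <- list(
    lt3_lt32 = list(
      c("congenital_anomalies", NA), c("injuries", NA),
      c("birth_asphyxia", NA), c("prematurity_complications", NA)
    ),
    ge3_lt32 = list(
      c("congenital_anomalies", NA), c("injuries", NA),
      c("birth_asphyxia", 7), c("tetanus", NA),
      c("severe_infection", NA), c("prematurity_complications", NA)
    ),
    lt3_ge32 = list(
      c("congenital_anomalies", NA), c("injuries", NA),
      c("birth_asphyxia", NA), c("severe_infection", NA),
      c("prematurity_complications", NA), c("other_specific", NA)
    ),
    ge3_ge32 = list(
      c("congenital_anomalies", NA), c("injuries", NA),
      c("birth_asphyxia", 7), c("tetanus", NA),
      c("severe_infection", NA), c("prematurity_complications", NA),
      c("other_specific", NA)
    )
  )
  purrr::imap_dfr(strata, function(slots, name) {
    tibble(
      stratum = name,
      rank = seq_along(slots),
      slot = purrr::map_chr(slots, 1),
      age_lt_days = as.numeric(purrr::map_chr(slots, 2))
    )
  })
}

# Expanded per-stratum resolution order with the composite slot unrolled into
# member causes (which inherit the slot's age condition, vacuously NA here).
expanded_hierarchy <- function() {
  hierarchy_table() |>
    dplyr::mutate(
      cause = purrr::map(.data$slot, function(s) {
        if (s == "severe_infection") severe_infection_causes() else s
      })
    ) |>
    tidyr::unnest_longer("cause") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(order = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("stratum", "order", "cause", "age_lt_days")
}

#' Locate a case in the assignment hierarchy's strata
#'
#' Maps age at death and gestational age to one of the four hierarchy
#' strata. Boundaries follow the strict-`<` convention: a death at exactly 3
#' completed days falls in the `ge3` band and a gestation of exactly 32
#' weeks in the `ge32` band.
#'
#' @param age_at_death_days Non-negative integer vector, completed days
#'   (0-28).
#' @param gestation_weeks Positive numeric vector; may contain `NA` if a
#'   `missing_gestation` fallback is set.
#' @param missing_gestation Policy for records with unknown gestation:
#'   `"error"` (default, refuse), `"assume_ge32"` or `"assume_lt32"`.
#' @return Character vector of stratum labels (`lt3_lt32`, `ge3_lt32`,
#'   `lt3_ge32`, `ge3_ge32`).
#' @examples
#' stratum_of(c(2, 3, 10), c(30, 32, 36))
#' @export
stratum_of <- function(age_at_death_days, gestation_weeks,
                       missing_gestation = c("error", "assume_ge32", "assume_lt32")) {
  missing_gestation <- match.arg(missing_gestation)
  if (any(is.na(age_at_death_days)) || any(age_at_death_days < 0)) {
    abort("`age_at_death_days` must be non-negative and non-missing.")
  }
  if (any(age_at_death_days > 28)) {
    abort("`age_at_death_days` exceeds 28: not a neonatal death.")
  }
  miss <- is.na(gestation_weeks)
  if (any(miss)) {
    if (missing_gestation == "error") {
      abort(paste0(
        "Missing gestation for ", sum(miss), " record(s); set ",
        "`missing_gestation` to \"assume_ge32\" or \"assume_lt32\" to band them."
      ))
    }
    gestation_weeks[miss] <- if (missing_gestation == "assume_ge32") 32 else 31
  }
  if (any(gestation_weeks <= 0)) abort("`gestation_weeks` must be positive.")
  paste0(
    ifelse(age_at_death_days < 3, "lt3", "ge3"), "_",
    ifelse(gestation_weeks < 32, "lt32", "ge32")
  )
}

#' Assign the primary cause of death for a table of cases
#'
#' Applies the stratified first-match hierarchy to each case: within the
#' case's stratum, the first cause whose eligibility flag (`elig_*` column)
#' is `TRUE` and whose age condition (if any) is satisfied becomes the
#' primary cause; a case meeting no case definition is `unexplained`.
#'
#' With `collapse_lt34 = TRUE`, an assignment of `birth_asphyxia` at
#' gestation below 34 weeks is re-labelled `prematurity_complications`,
#' reflecting the convention that a very premature baby who did not breathe
#' at birth is better attributed to prematurity than to asphyxia. The rule
#' is off by default.
#'
#' @param cases Data frame with columns `case_id`, `age_at_death_days`,
#'   `gestation_weeks`, and one logical `elig_<cause>` column per assignable
#'   cause (absent flag columns are treated as all-`FALSE`).
#' @param collapse_lt34 Logical; apply the asphyxia-into-prematurity
#'   collapse below `collapse_threshold_weeks`.
#' @param missing_gestation Passed to [stratum_of()].
#' @param collapse_threshold_weeks Gestation threshold (weeks) for the
#'   collapse rule; default 34.
#' @return A tibble with columns `case_id`, `assigned_cause`, `stratum`,
#'   `collapse_applied`.
#' @examples
#' cases <- tibble::tibble(
#'   case_id = c("a", "b"), age_at_death_days = c(1, 10),
#'   gestation_weeks = c(30, 36),
#'   elig_birth_asphyxia = c(FALSE, TRUE),
#'   elig_tetanus = c(FALSE, TRUE),
#'   elig_prematurity_complications = c(TRUE, FALSE)
#' )
#' assign_causes(cases)
#' @export
assign_causes <- function(cases, collapse_lt34 = FALSE,
                          missing_gestation = c("error", "assume_ge32", "assume_lt32"),
                          collapse_threshold_weeks = 34) {
  check_data_frame(cases, "cases")
  check_columns(cases, c("case_id", "age_at_death_days", "gestation_weeks"),
                "cases")
  check_unique_ids(cases$case_id, "cases")

  elig_cols <- grep("^elig_", names(cases), value = TRUE)
  flagged <- sub("^elig_", "", elig_cols)
  check_cause_codes(flagged, assignable_causes(), what = "eligibility flag")

  n <- nrow(cases)
  age <- cases$age_at_death_days
  stratum <- stratum_of(age, cases$gestation_weeks,
                        missing_gestation = missing_gestation)

  elig <- matrix(FALSE, n, length(assignable_causes()),
                 dimnames = list(NULL, assignable_causes()))
  for (col in elig_cols) {
    v <- cases[[col]]
    if (!is.logical(v)) abort(sprintf("Column `%s` must be logical.", col))
    elig[, sub("^elig_", "", col)] <- !is.na(v) & v
  }

  plan <- expanded_hierarchy()
  assigned <- rep(NA_character_, n)
  for (s in unique(stratum)) {
    rows <- plan[plan$stratum == s, ]
    in_s <- stratum == s
    for (i in seq_len(nrow(rows))) {
      cond_ok <- if (is.na(rows$age_lt_days[i])) TRUE else age < rows$age_lt_days[i]
      hit <- in_s & is.na(assigned) & elig[, rows$cause[i]] & cond_ok
      assigned[hit] <- rows$cause[i]
    }
  }
  assigned[is.na(assigned)] <- "unexplained"

  collapse_applied <- rep(FALSE, n)
  if (isTRUE(collapse_lt34)) {
    g <- cases$gestation_weeks
    collapse_applied <- assigned == "birth_asphyxia" &
      !is.na(g) & g < collapse_threshold_weeks
    assigned[collapse_applied] <- "prematurity_complications"
  }

  tibble(
    case_id = cases$case_id,
    assigned_cause = assigned,
    stratum = stratum,
    collapse_applied = collapse_applied
  )
}

#' Assign the primary cause for a single case
#'
#' Scalar convenience wrapper around [assign_causes()].
#'
#' @param age_at_death_days Completed days of age at death (0-28).
#' @param gestation_weeks Gestational age in weeks (or `NA`).
#' @param eligibility Named logical vector of case-definition flags, names
#'   being assignable cause codes (unnamed causes default to `FALSE`).
#' @inheritParams assign_causes
#' @return A single cause code (character).
#' @examples
#' assign_primary_cause(10, 36, c(birth_asphyxia = TRUE, tetanus = TRUE))
#' @export
assign_primary_cause <- function(age_at_death_days, gestation_weeks, eligibility,
                                 collapse_lt34 = FALSE,
                                 missing_gestation = c("error", "assume_ge32", "assume_lt32"),
                                 collapse_threshold_weeks = 34) {
  if (is.null(names(eligibility)) || !is.logical(eligibility)) {
    abort("`eligibility` must be a named logical vector.")
  }
  row <- tibble(
    case_id = "case", age_at_death_days = age_at_death_days,
    gestation_weeks = gestation_weeks
  )
  for (cause in names(eligibility)) {
    row[[paste0("elig_", cause)]] <- unname(eligibility[[cause]])
  }
  assign_causes(row, collapse_lt34 = collapse_lt34,
                missing_gestation = missing_gestation,
                collapse_threshold_weeks = collapse_threshold_weeks)$assigned_cause
}
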