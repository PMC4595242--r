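# High-level result objects: va_accuracy (per-cause diagnostic accuracy of
# VA against the reference standard), va_csmf (paired CSMF tables), and the
# end-to-end pipeline wrapper.

# The five leading causes reported in the study's accuracy table.
default_targets <- function() {
  c("congenital_anomalies", "prematurity_complications", "birth_asphyxia",
    "tetanus", "severe_infection")
}

#' Per-cause diagnostic accuracy of VA diagnoses
#'
#' The main validation computation: for each target cause, builds the 2x2
#' table of VA against reference positivity, computes sensitivity,
#' specificity, PPV and NPV with Wilson score intervals, and a Pearson
#' chi-square test of association.
#'
#' @param pairs Paired label table from [paired_labels()].
#' @param targets Target causes; defaults to the five leading causes
#'   (congenital anomalies, prematurity complications, birth asphyxia,
#'   tetanus and the severe-infection composite).
#' @param confidence Confidence level for score intervals.
#' @param correct Logical; Yates continuity correction for the chi-square.
#' @return An object of class `va_accuracy`: a list with `accuracy` (tibble
#'   of counts, estimates and tests per cause), `n_pairs`,
#'   `overall_agreement` and `confidence`. Use [tidy()] for a long tibble of
#'   estimates, [glance()] for the one-row summary, [autoplot()] to plot.
#' @examples
#' pairs <- tibble::tibble(
#'   case_id = as.character(1:4),
#'   reference_cause = c("sepsis", "sepsis", "tetanus", "birth_asphyxia"),
#'   va_cause = c("sepsis", "tetanus", "tetanus", "birth_asphyxia")
#' )
#' va_accuracy(pairs, targets = c("tetanus", "severe_infection"))
#' @export
va_accuracy <- function(pairs, targets = default_targets(),
                        confidence = 0.95, correct = FALSE) {
  counts <- contingency(pairs, targets)
  acc <- diagnostic_accuracy(counts, confidence = confidence)
  tests <- purrr::map_dfr(
    seq_len(nrow(counts)),
    function(i) chi_square_2x2(counts[i, ], correct = correct)
  )
  out <- list(
    accuracy = dplyr::left_join(acc, tests, by = "cause"),
    n_pairs = nrow(pairs),
    overall_agreement = overall_agreement(pairs),
    confidence = confidence
  )
  structure(out, class = "va_accuracy")
}

#' @export
print.va_accuracy <- function(x, ...) {
  cat(sprintf(
    "Verbal autopsy diagnostic accuracy (%d paired cases, %.0f%% CI)\n",
    x$n_pairs, 100 * x$confidence
  ))
  cat(sprintf("Overall cause agreement: %.1f%%\n\n",
              round_half_up(100 * x$overall_agreement, 1)))
  fmt <- function(p, lo, hi) {
    ifelse(is.na(p), "   --   ",
           sprintf("%5.1f (%.1f-%.1f)", round_half_up(100 * p, 1),
                   round_half_up(100 * lo, 1), round_half_up(100 * hi, 1)))
  }
  a <- x$accuracy
  df <- data.frame(
    cause = a$cause,
    sensitivity = fmt(a$sensitivity, a$sensitivity_low, a$sensitivity_high),
    specificity = fmt(a$specificity, a$specificity_low, a$specificity_high),
    ppv = fmt(a$ppv, a$ppv_low, a$ppv_high),
    npv = fmt(a$npv, a$npv_low, a$npv_high)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tidy a va_accuracy object
#'
#' @param x A [va_accuracy()] object.
#' @param ... Unused.
#' @return A long tibble: `cause`, `metric` (sensitivity/specificity/ppv/
#'   npv), `estimate`, `conf.low`, `conf.high` (proportions, full
#'   precision).
#' @export
tidy.va_accuracy <- function(x, ...) {
  purrr::map_dfr(c("sensitivity", "specificity", "ppv", "npv"), function(m) {
    tibble(
      cause = x$accuracy$cause,
      metric = m,
      estimate = x$accuracy[[m]],
      conf.low = x$accuracy[[paste0(m, "_low")]],
      conf.high = x$accuracy[[paste0(m, "_high")]]
    )
  })
}

#' Glance at a va_accuracy object
#'
#' @param x A [va_accuracy()] object.
#' @param ... Unused.
#' @return One-row tibble: `n_pairs`, `n_causes`, `overall_agreement`,
#'   `confidence`.
#' @export
glance.va_accuracy <- function(x, ...) {
  tibble(
    n_pairs = x$n_pairs,
    n_causes = nrow(x$accuracy),
    overall_agreement = x$overall_agreement,
    confidence = x$confidence
  )
}

#' Compare CSMFs between reference and VA diagnoses
#'
#' Side-by-side cause-specific mortality fractions computed from the
#' reference-standard and VA final diagnoses of the same cohort.
#'
#' @param reference,va Character vectors of final causes, or data frames
#'   with a `final_cause` column.
#' @return An object of class `va_csmf`: a tibble with columns `cause`,
#'   `n_reference`, `fraction_reference`, `n_va`, `fraction_va` (absent
#'   causes filled with zeros).
#' @export
csmf_compare <- function(reference, va) {
  ref <- csmf(reference)
  vaa <- csmf(va)
  out <- dplyr::full_join(
    dplyr::rename(ref, n_reference = "n", fraction_reference = "fraction"),
    dplyr::rename(vaa, n_va = "n", fraction_va = "fraction"),
    by = "cause"
  ) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ tidyr::replace_na(.x, 0))) |>
    dplyr::mutate(cause = factor(.data$cause, levels = va_causes()$cause)) |>
    dplyr::arrange(.data$cause) |>
    dplyr::mutate(cause = as.character(.data$cause))
  class(out) <- c("va_csmf", class(out))
  out
}

#' Run the full validation pipeline on adjudicated review tables
#'
#' Adjudicates the reference-standard and VA reviewer tables, pairs the
#' final diagnoses, and computes the adjudication summaries, CSMF
#' comparison, overall agreement and per-cause diagnostic accuracy.
#'
#' @param reference_reviews,va_reviews Long reviewer tables (see
#'   [adjudicate()]).
#' @param targets,confidence,correct Passed to [va_accuracy()].
#' @return An object of class `va_report`: a list with `adjudication`
#'   (tibbles for reference and VA sides), `diagnoses` (paired final
#'   labels), `csmf` (a [csmf_compare()] table) and `accuracy` (a
#'   [va_accuracy()] object).
#' @export
run_pipeline <- function(reference_reviews, va_reviews,
                         targets = default_targets(),
                         confidence = 0.95, correct = FALSE) {
  ref <- adjudicate(reference_reviews)
  vaa <- adjudicate(va_reviews)
  pairs <- paired_labels(ref, vaa)
  structure(
    list(
      adjudication = list(
        reference = summarize_adjudication(ref),
        va = summarize_adjudication(vaa)
      ),
      diagnoses = pairs,
      csmf = csmf_compare(ref, vaa),
      accuracy = va_accuracy(pairs, targets = targets,
                             confidence = confidence, correct = correct)
    ),
    class = "va_report"
  )
}

#' @export
print.va_report <- function(x, ...) {
  cat("== Adjudication ==\n")
  cat("reference: "); print(x$adjudication$reference)
  cat("va:        "); print(x$adjudication$va)
  cat("\n== CSMF ==\n")
  print(as_tibble(x$csmf), n = Inf)
  cat("\n== Accuracy ==\n")
  print(x$accuracy)
  invisible(x)
}
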