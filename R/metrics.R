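# Per-cause diagnostic accuracy of VA diagnoses against the clinical
# reference standard: 2x2 contingency tables, sensitivity / specificity /
# PPV / NPV with Wilson score intervals, CSMF tables, overall agreement and
# chi-square comparisons.

#' Pair reference and VA diagnoses by case
#'
#' Joins the adjudicated reference-standard diagnoses and the adjudicated VA
#' diagnoses on `case_id`. Both sides must cover exactly the same cases.
#'
#' @param reference,va Data frames with columns `case_id` and `final_cause`
#'   (a `cause` column is also accepted).
#' @return A tibble with columns `case_id`, `reference_cause`, `va_cause`.
#' @export
paired_labels <- function(reference, va) {
  pick <- function(x, arg) {
    check_data_frame(x, arg)
    check_columns(x, "case_id", arg)
    col <- intersect(c("final_cause", "cause"), names(x))[1]
    if (is.na(col)) {
      abort(sprintf("`%s` needs a `final_cause` (or `cause`) column.", arg))
    }
    check_unique_ids(x$case_id, arg)
    check_cause_codes(x[[col]], final_labels(), what = "final cause")
    tibble(case_id = x$case_id, cause = x[[col]])
  }
  ref <- pick(reference, "reference")
  vaa <- pick(va, "va")
  only_ref <- setdiff(ref$case_id, vaa$case_id)
  only_va <- setdiff(vaa$case_id, ref$case_id)
  if (length(only_ref) + length(only_va) > 0) {
    abort(sprintf(
      "case_id mismatch between reference and va: %d only in reference (%s), %d only in va (%s).",
      length(only_ref), paste(head(only_ref, 5), collapse = ", "),
      length(only_va), paste(head(only_va, 5), collapse = ", ")
    ))
  }
  dplyr::inner_join(
    dplyr::rename(ref, reference_cause = "cause"),
    dplyr::rename(vaa, va_cause = "cause"),
    by = "case_id"
  )
}

# TRUE where a label counts as positive for the target; terminal labels
# (unexplained/unclassifiable) are negative for every specific cause, so
# every 2x2 table totals the full number of pairs.
label_positive <- function(labels, target) {
  if (target == "severe_infection") {
    labels %in% severe_infection_causes()
  } else {
    labels == target
  }
}

#' Per-cause 2x2 contingency counts
#'
#' Cross-tabulates target-positivity of the VA diagnosis (test) against the
#' reference diagnosis (truth) for one or more target causes. A case is
#' positive on a side when its label equals the target, or, for the
#' `"severe_infection"` composite, is any of sepsis, meningitis, pneumonia
#' or diarrhea. Unexplained and unclassifiable labels are negative for every
#' target, so `tp + fp + tn + fn` always equals the number of pairs.
#'
#' @param pairs Paired label table from [paired_labels()].
#' @param targets Character vector of assignable cause codes and/or
#'   `"severe_infection"`.
#' @return A tibble with one row per target: `cause`, `tp`, `fp`, `tn`, `fn`.
#' @export
contingency <- function(pairs, targets) {
  check_data_frame(pairs, "pairs")
  check_columns(pairs, c("reference_cause", "va_cause"), "pairs")
  check_cause_codes(targets, c(assignable_causes(), "severe_infection"),
                    what = "target cause")
  purrr::map_dfr(targets, function(target) {
    ref_pos <- label_positive(pairs$reference_cause, target)
    va_pos <- label_positive(pairs$va_cause, target)
    tibble(
      cause = target,
      tp = sum(ref_pos & va_pos),
      fp = sum(!ref_pos & va_pos),
      tn = sum(!ref_pos & !va_pos),
      fn = sum(ref_pos & !va_pos)
    )
  })
}

#' Wilson score interval for a binomial proportion
#'
#' Confidence interval obtained by inverting the normal-approximation score
#' test, without continuity correction. Unlike the Wald interval it is well
#' behaved near 0 and 1 and never leaves `[0, 1]`; it is the interval form
#' that reproduces published VA validation tables computed by this package's
#' conventions.
#'
#' @param successes,trials Integer vectors, `0 <= successes <= trials`,
#'   `trials > 0`.
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @return A tibble with columns `lower`, `upper`.
#' @examples
#' score_interval(147, 176)
#' @export
score_interval <- function(successes, trials, confidence = 0.95) {
  if (length(confidence) != 1 || confidence <= 0 || confidence >= 1) {
    abort("`confidence` must be a single value in (0, 1).")
  }
  if (any(trials <= 0)) abort("`trials` must be positive.")
  if (any(successes < 0) || any(successes > trials)) {
    abort("`successes` must lie in [0, trials].")
  }
  z <- qnorm(1 - (1 - confidence) / 2)
  n <- trials
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble(
    lower = pmax(0, centre - half),
    upper = pmin(1, centre + half)
  )
}

#' Sensitivity, specificity and predictive values with score intervals
#'
#' Computes the four standard diagnostic-accuracy proportions from per-cause
#' 2x2 counts, each with its Wilson score interval. A proportion with a zero
#' denominator (e.g. sensitivity when no reference-positive case exists) is
#' returned as `NA` with a warning rather than silently as 0.
#'
#' @param counts Data frame with columns `cause`, `tp`, `fp`, `tn`, `fn`
#'   (one row per cause), as from [contingency()].
#' @param confidence Confidence level for the intervals; default 0.95.
#' @return A tibble with the count columns plus, for each of `sensitivity`,
#'   `specificity`, `ppv`, `npv`: the proportion and `_low`/`_high` interval
#'   bounds (all on the 0-1 scale, full precision).
#' @examples
#' diagnostic_accuracy(
#'   tibble::tibble(cause = "birth_asphyxia", tp = 147, fp = 41, tn = 409, fn = 29)
#' )
#' @export
diagnostic_accuracy <- function(counts, confidence = 0.95) {
  check_data_frame(counts, "counts")
  check_columns(counts, c("cause", "tp", "fp", "tn", "fn"), "counts")
  cells <- as.matrix(counts[, c("tp", "fp", "tn", "fn")])
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("`tp`, `fp`, `tn`, `fn` must be non-negative integers.")
  }

  one <- function(x, n, metric) {
    est <- rep(NA_real_, length(n))
    lo <- rep(NA_real_, length(n))
    hi <- rep(NA_real_, length(n))
    ok <- n > 0
    if (any(!ok)) {
      warn(sprintf(
        "Zero denominator for %s in %d cause(s); estimate undefined (NA).",
        metric, sum(!ok)
      ))
    }
    if (any(ok)) {
      est[ok] <- x[ok] / n[ok]
      ci <- score_interval(x[ok], n[ok], confidence)
      lo[ok] <- ci$lower
      hi[ok] <- ci$upper
    }
    tibble(est, lo, hi) |>
      setNames(c(metric, paste0(metric, "_low"), paste0(metric, "_high")))
  }

  dplyr::bind_cols(
    as_tibble(counts[, c("cause", "tp", "fp", "tn", "fn")]),
    one(counts$tp, counts$tp + counts$fn, "sensitivity"),
    one(counts$tn, counts$tn + counts$fp, "specificity"),
    one(counts$tp, counts$tp + counts$fp, "ppv"),
    one(counts$tn, counts$tn + counts$fn, "npv")
  )
}

#' Cause-specific mortality fractions
#'
#' Tabulates final diagnoses into per-cause counts and fractions of all
#' deaths (the CSMF).
#'
#' @param labels Character vector of final cause labels, or a data frame
#'   with a `final_cause` (or `cause`) column.
#' @return A tibble with columns `cause`, `n`, `fraction`, ordered by the
#'   taxonomy; only causes present in the data appear. `fraction` is
#'   full-precision `n / total`.
#' @examples
#' csmf(c("sepsis", "sepsis", "birth_asphyxia"))
#' @export
csmf <- function(labels) {
  if (is.data.frame(labels)) {
    col <- intersect(c("final_cause", "cause"), names(labels))[1]
    if (is.na(col)) {
      abort("`labels` needs a `final_cause` (or `cause`) column.")
    }
    labels <- labels[[col]]
  }
  if (length(labels) == 0) abort("`labels` must be non-empty.")
  check_cause_codes(labels, final_labels(), what = "final cause")
  tibble(cause = labels) |>
    dplyr::count(.data$cause) |>
    dplyr::mutate(
      cause = factor(.data$cause, levels = va_causes()$cause)
    ) |>
    dplyr::arrange(.data$cause) |>
    dplyr::mutate(
      cause = as.character(.data$cause),
      fraction = .data$n / sum(.data$n)
    )
}

#' Overall case-level agreement between reference and VA diagnoses
#'
#' The fraction of paired cases whose VA final cause is identical to the
#' reference final cause.
#'
#' @param pairs Paired label table from [paired_labels()].
#' @return A single proportion.
#' @export
overall_agreement <- function(pairs) {
  check_data_frame(pairs, "pairs")
  check_columns(pairs, c("reference_cause", "va_cause"), "pairs")
  if (nrow(pairs) == 0) abort("`pairs` must be non-empty.")
  mean(pairs$reference_cause == pairs$va_cause)
}

#' Chi-square test on a per-cause 2x2 table
#'
#' Pearson chi-square test of association between reference and VA
#' target-positivity, on the 2x2 table `[tp fn; fp tn]`. No continuity
#' correction by default; set `correct = TRUE` for the Yates-corrected
#' statistic. Warns when any expected cell count is below 5.
#'
#' @param counts One-row data frame with columns `tp`, `fp`, `tn`, `fn` (a
#'   `cause` column is carried through if present).
#' @param correct Logical; apply the Yates continuity correction.
#' @return A tibble with columns (`cause`,) `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  check_data_frame(counts, "counts")
  check_columns(counts, c("tp", "fp", "tn", "fn"), "counts")
  if (nrow(counts) != 1) abort("`counts` must be a single row; see purrr::map_dfr for batches.")
  m <- matrix(c(counts$tp, counts$fp, counts$fn, counts$tn), nrow = 2,
              dimnames = list(reference = c("pos", "neg"),
                              va = c("pos", "neg")))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Degenerate 2x2 table: a row or column margin is zero.")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    warn("Expected cell count below 5; chi-square approximation may be poor.")
  }
  fit <- suppressWarnings(chisq.test(m, correct = correct))
  out <- tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = unname(fit$p.value)
  )
  if ("cause" %in% names(counts)) {
    out <- dplyr::bind_cols(tibble(cause = counts$cause), out)
  }
  out
}
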