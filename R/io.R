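# Delimited-text I/O with strict schema validation. All tables are
# comma-separated UTF-8 with a mandatory header; booleans are written as
# true/false. Validation errors name the offending row and value.

bad_rows_msg <- function(rows, values) {
  paste(sprintf("row %d: %s", head(rows, 5), head(values, 5)), collapse = "; ")
}

validate_cause_column <- function(x, allowed, col, file) {
  bad <- which(!is.na(x) & !(x %in% allowed))
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown cause code(s) in column `%s` of %s: %s.",
      col, file, bad_rows_msg(bad, sQuote(x[bad]))
    ))
  }
}

#' Read a case-record table
#'
#' Reads and validates a CSV of deceased-neonate case records: one row per
#' case with identifiers, age at death in completed days (0-28), gestation
#' in weeks (empty = missing), sex, birth weight, data source, and one
#' logical `elig_<cause>` column per assignable cause-of-death case
#' definition.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of case records.
#' @export
read_cases <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, c("case_id", "age_at_death_days", "gestation_weeks",
                     "sex", "birth_weight_g", "source"), path)
  x$case_id <- as.character(x$case_id)
  check_unique_ids(x$case_id, path)

  bad_age <- which(is.na(x$age_at_death_days) | x$age_at_death_days < 0 |
                     x$age_at_death_days > 28)
  if (length(bad_age) > 0) {
    abort(sprintf(
      "`age_at_death_days` must be in 0-28 in %s: %s.",
      path, bad_rows_msg(bad_age, x$age_at_death_days[bad_age])
    ))
  }
  bad_sex <- which(!x$sex %in% c("male", "female", "unknown"))
  if (length(bad_sex) > 0) {
    abort(sprintf("Invalid `sex` in %s: %s.", path,
                  bad_rows_msg(bad_sex, sQuote(x$sex[bad_sex]))))
  }
  bad_src <- which(!x$source %in% c("hospital", "verbal_autopsy"))
  if (length(bad_src) > 0) {
    abort(sprintf("Invalid `source` in %s: %s.", path,
                  bad_rows_msg(bad_src, sQuote(x$source[bad_src]))))
  }

  elig_cols <- grep("^elig_", names(x), value = TRUE)
  check_cause_codes(sub("^elig_", "", elig_cols), assignable_causes(),
                    what = "eligibility flag")
  for (col in elig_cols) {
    if (!is.logical(x[[col]])) {
      abort(sprintf("Column `%s` in %s must be true/false.", col, path))
    }
  }
  x
}

#' Read a reviewer-assignment table
#'
#' Reads and validates a CSV of reviewer cause calls with columns
#' `case_id`, `reviewer_id`, `round` (`primary`/`arbiter`) and `cause`.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble suitable for [adjudicate()].
#' @export
read_reviews <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, c("case_id", "reviewer_id", "round", "cause"), path)
  x$case_id <- as.character(x$case_id)
  bad_round <- which(!x$round %in% c("primary", "arbiter"))
  if (length(bad_round) > 0) {
    abort(sprintf("Invalid `round` in %s: %s.", path,
                  bad_rows_msg(bad_round, sQuote(x$round[bad_round]))))
  }
  validate_cause_column(x$cause, reviewable_causes(), "cause", path)
  x
}

#' Read an adjudicated-diagnosis table
#'
#' Reads and validates a CSV of final per-case diagnoses with columns
#' `case_id` and `final_cause` (optionally `resolution`).
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of adjudicated diagnoses.
#' @export
read_diagnoses <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, c("case_id", "final_cause"), path)
  x$case_id <- as.character(x$case_id)
  check_unique_ids(x$case_id, path)
  validate_cause_column(x$final_cause, final_labels(), "final_cause", path)
  x
}

#' Write a table as CSV
#'
#' Comma-separated UTF-8 with a header row; logical columns serialised as
#' `true`/`false` so they survive a read/write round trip.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.logical),
                                      ~ ifelse(.x, "true", "false")))
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Write a full validation report to a directory
#'
#' Writes the three result tables of a [run_pipeline()] report as CSVs
#' (`accuracy.csv`, `csmf.csv`, `adjudication.csv`) plus a machine-readable
#' JSON twin (`report.json`) with the adjudication summaries, the CSMF
#' comparison, overall agreement and the per-cause accuracy estimates
#' (percentages half-up to `digits` decimals, with raw counts).
#'
#' @param report A `va_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @param digits Reporting precision for percentages; default 1.
#' @return The paths written, invisibly.
#' @export
write_validation_report <- function(report, dir, digits = 1) {
  if (!inherits(report, "va_report")) {
    abort("`report` must be a `va_report` from run_pipeline().")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  adj <- dplyr::bind_rows(
    dplyr::mutate(report$adjudication$reference, side = "reference",
                  .before = 1),
    dplyr::mutate(report$adjudication$va, side = "va", .before = 1)
  )
  acc <- report$accuracy$accuracy
  pct <- function(x) round_half_up(100 * x, digits)

  paths <- c(
    accuracy = file.path(dir, "accuracy.csv"),
    csmf = file.path(dir, "csmf.csv"),
    adjudication = file.path(dir, "adjudication.csv"),
    json = file.path(dir, "report.json")
  )
  write_table(acc, paths["accuracy"])
  write_table(as_tibble(report$csmf), paths["csmf"])
  write_table(adj, paths["adjudication"])

  json <- list(
    n_pairs = report$accuracy$n_pairs,
    overall_agreement_pct = pct(report$accuracy$overall_agreement),
    adjudication = adj,
    csmf = dplyr::mutate(
      as_tibble(report$csmf),
      fraction_reference = pct(.data$fraction_reference),
      fraction_va = pct(.data$fraction_va)
    ),
    accuracy = dplyr::mutate(
      acc,
      dplyr::across(dplyr::matches("^(sensitivity|specificity|ppv|npv)"), pct)
    )
  )
  jsonlite::write_json(json, paths["json"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
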