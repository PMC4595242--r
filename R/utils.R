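#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used in epidemiological
#' report tables (base `round()` rounds half to even). Used wherever the
#' package formats percentages for reporting; internal computations keep
#' full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 78.85), c(0, 0, 1))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # eps guard: binary representation can land an exact .5 a hair below it
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# shared input checks -------------------------------------------------------

check_data_frame <- function(x, arg) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame, not %s.", arg, class(x)[1]))
  }
  invisible(x)
}

check_columns <- function(x, cols, arg) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      arg, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

check_unique_ids <- function(ids, arg) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf(
      "Duplicate case_id(s) in `%s`: %s.",
      arg, paste(head(dup, 5), collapse = ", ")
    ))
  }
  invisible(ids)
}

check_probability <- function(x, name, allow_zero = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (any(!is.finite(x)) || any(!lo_ok) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}
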