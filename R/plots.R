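# ggplot2 displays for the two result types.

#' Plot per-cause diagnostic accuracy
#'
#' Point estimates with Wilson score interval bars, faceted by metric.
#'
#' @param object A [va_accuracy()] object.
#' @param metrics Which metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.va_accuracy <- function(object,
                                 metrics = c("sensitivity", "specificity",
                                             "ppv", "npv"),
                                 ...) {
  dat <- tidy(object) |>
    dplyr::filter(.data$metric %in% metrics, !is.na(.data$estimate))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$cause)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(
      x = sprintf("estimate (%.0f%% score interval)", 100 * object$confidence),
      y = NULL,
      title = "Verbal autopsy diagnostic accuracy vs reference standard"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a CSMF comparison
#'
#' Side-by-side bars of the cause-specific mortality fractions under the
#' reference-standard and VA diagnoses.
#'
#' @param object A [csmf_compare()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.va_csmf <- function(object, ...) {
  dat <- as_tibble(object) |>
    tidyr::pivot_longer(
      c("fraction_reference", "fraction_va"),
      names_to = "side", names_prefix = "fraction_", values_to = "fraction"
    )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$fraction, y = .data$cause, fill = .data$side)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "cause-specific mortality fraction", y = NULL,
                  fill = NULL,
                  title = "CSMF: reference standard vs verbal autopsy") +
    ggplot2::theme_minimal()
}

#' @export
plot.va_accuracy <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.va_csmf <- function(x, ...) print(autoplot(x, ...))
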