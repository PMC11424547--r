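# ggplot2 views of the result tables. Figures are plain data views of the
# same tibbles the TSV writers emit.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest-style plot of disproportionality scores
#'
#' Reporting odds ratios with 95% confidence intervals on a log scale, one
#' row per term, strongest signals on top.
#'
#' @param object A `disprop_scores` tibble (optionally screened).
#' @param top_k Terms shown (by ROR).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disprop_scores <- function(object, top_k = 30, ...) {
  df <- object |>
    dplyr::filter(!is.na(.data$ror)) |>
    dplyr::arrange(dplyr::desc(.data$ror)) |>
    head(top_k)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$ror, y = stats::reorder(.data$term, .data$ror)
  )) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ror_lo, xmax = .data$ror_hi), height = 0.25
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Reporting odds ratio (95% CI)", y = NULL)
}

#' Histogram of time-to-onset bins
#'
#' @param onset Records from [onset_records()].
#' @return A ggplot object.
#' @export
plot_onset_bins <- function(onset) {
  bins <- onset_summary(onset)$bins
  bins$bin <- factor(bins$bin, levels = ONSET_BIN_LEVELS)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Days from therapy start to event", y = "Reports")
}

#' Yearly report counts
#'
#' @param reports A report tibble with a `year` column.
#' @return A ggplot object.
#' @export
plot_reports_by_year <- function(reports) {
  df <- dplyr::count(reports, .data$year)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Reporting year", y = "Reports")
}

#' Pediatric-vs-adult subgroup forest plot
#'
#' @param subgroup Output of [subgroup_disprop()].
#' @param top_k Terms shown (by pediatric count).
#' @return A ggplot object.
#' @export
plot_subgroup <- function(subgroup, top_k = 30) {
  df <- head(dplyr::filter(subgroup, !is.na(.data$ror)), top_k)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$ror, y = stats::reorder(.data$term, .data$ror),
    colour = .data$direction
  )) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ror_lo, xmax = .data$ror_hi), height = 0.25
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Pediatric vs adult reporting odds ratio (95% CI)",
                  y = NULL, colour = "Enriched in")
}
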