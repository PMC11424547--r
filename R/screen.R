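#' Signal-screening threshold policy
#'
#' The standard positive-signal criteria for the four algorithms:
#'
#' * ROR: lower 95% CI bound > 1,
#' * PRR: PRR >= 2 and chi-squared >= 4,
#' * BCPNN: IC025 > 0,
#' * MGPS: EBGM05 > 2,
#'
#' combined either conjunctively (`"all_four"`, the PT-level consensus
#' rule) or disjunctively (`"any_one"`, used at SOC level where the
#' conjunction is rarely attainable). Every threshold is overridable.
#'
#' @param min_count Minimum report count per term (enforced upstream by
#'   [build_contingency()], re-checked here).
#' @param ror_lo_gt Lower ROR CI bound must exceed this.
#' @param prr_ge,chi2_ge PRR and chi-squared minima.
#' @param ic025_gt IC025 must exceed this.
#' @param ebgm05_gt EBGM05 must exceed this.
#' @param combination `"all_four"` or `"any_one"`.
#' @return A `threshold_policy` list.
#' @export
threshold_policy <- function(min_count = 5, ror_lo_gt = 1, prr_ge = 2,
                             chi2_ge = 4, ic025_gt = 0, ebgm05_gt = 2,
                             combination = c("all_four", "any_one")) {
  combination <- match.arg(combination)
  if (min_count < 1 || ror_lo_gt <= 0 || prr_ge <= 0 || chi2_ge <= 0 ||
      ebgm05_gt <= 0) {
    stop_config("threshold policy values must be strictly positive (min_count >= 1)")
  }
  structure(
    list(min_count = min_count, ror_lo_gt = ror_lo_gt, prr_ge = prr_ge,
         chi2_ge = chi2_ge, ic025_gt = ic025_gt, ebgm05_gt = ebgm05_gt,
         combination = combination),
    class = "threshold_policy"
  )
}

#' Apply per-algorithm thresholds and the combination rule
#'
#' Adds a logical verdict per algorithm plus the combined `signal` verdict.
#' An undefined statistic (NA, e.g. zero-cell table with corrections off)
#' yields a `FALSE` verdict and is recorded in the `undefined` column, so
#' missing evidence never counts in favour of a signal.
#'
#' @param scores A [disprop_scores()] tibble.
#' @param policy A [threshold_policy()].
#' @return `scores` with columns `ror_pos`, `prr_pos`, `bcpnn_pos`,
#'   `mgps_pos`, `undefined` (comma-separated algorithm names whose
#'   statistic was undefined, `""` if none) and `signal`.
#' @export
screen_signals <- function(scores, policy = threshold_policy()) {
  stopifnot(inherits(policy, "threshold_policy"))
  out <- scores |>
    dplyr::filter(.data$a >= policy$min_count) |>
    dplyr::mutate(
      ror_pos = !is.na(.data$ror_lo) & .data$ror_lo > policy$ror_lo_gt,
      prr_pos = !is.na(.data$prr) & !is.na(.data$chi2) &
        .data$prr >= policy$prr_ge & .data$chi2 >= policy$chi2_ge,
      bcpnn_pos = !is.na(.data$ic025) & .data$ic025 > policy$ic025_gt,
      mgps_pos = !is.na(.data$ebgm05) & .data$ebgm05 > policy$ebgm05_gt
    )
  und <- cbind(
    ror = is.na(out$ror_lo),
    prr = is.na(out$prr) | is.na(out$chi2),
    bcpnn = is.na(out$ic025),
    mgps = is.na(out$ebgm05)
  )
  out$undefined <- apply(und, 1, function(row) {
    paste(colnames(und)[row], collapse = ",")
  })
  out$signal <- if (policy$combination == "all_four") {
    out$ror_pos & out$prr_pos & out$bcpnn_pos & out$mgps_pos
  } else {
    out$ror_pos | out$prr_pos | out$bcpnn_pos | out$mgps_pos
  }
  out
}

#' Rank flagged terms for reporting
#'
#' Stable descending sort of the flagged terms by report count or EBGM,
#' ties broken by the other key and then alphabetically by term, truncated
#' to the top `top_k` — the shape of published top-30 signal tables.
#'
#' @param screened Output of [screen_signals()].
#' @param by Primary sort key: `"report_count"` (cell a) or `"ebgm"`.
#' @param top_k Number of rows to keep; must be >= 1.
#' @param flagged_only Keep only rows with `signal == TRUE` (default).
#' @return The ranked, truncated tibble.
#' @export
rank_signals <- function(screened, by = c("report_count", "ebgm"),
                         top_k = 30, flagged_only = TRUE) {
  by <- match.arg(by)
  if (!is.numeric(top_k) || top_k < 1) {
    stop_config("`top_k` must be >= 1")
  }
  out <- if (flagged_only) {
    dplyr::filter(screened, .data$signal)
  } else {
    screened
  }
  out <- if (by == "report_count") {
    dplyr::arrange(out, dplyr::desc(.data$a), dplyr::desc(.data$ebgm),
                   .data$term)
  } else {
    dplyr::arrange(out, dplyr::desc(.data$ebgm), dplyr::desc(.data$a),
                   .data$term)
  }
  head(out, top_k)
}
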