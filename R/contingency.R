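#' Build report-level 2x2 contingency tables per term
#'
#' For every term (preferred term, or system organ class when
#' `level = "soc"`) the classic pharmacovigilance 2x2 table is formed
#' against the rest of the database:
#'
#' * `a` — target-drug reports mentioning the term,
#' * `b` — target-drug reports without the term,
#' * `c` — other-drug reports mentioning the term,
#' * `d` — other-drug reports without the term.
#'
#' The counting unit is the deduplicated report: a report contributes at
#' most 1 to `a` (or `c`) for a given term no matter how many times the
#' term — or, at SOC level, how many of its PTs — appears on the report.
#' With `unit = "pair"` the marginal totals `a + b` and `c + d` instead
#' count distinct (report, term) pairs, which matches databases whose
#' denominators are reaction records rather than reports; cell `a` itself
#' is unchanged. Tables are emitted only for terms with `a >= min_count`
#' (default 5 reports), the usual guard against spurious signals from very
#' rare terms.
#'
#' @param reports Deduplicated report tibble.
#' @param reactions Reaction tibble with `pt` (and `soc` when
#'   `level = "soc"`; see [map_pts()]).
#' @param target_ids PRIMARYIDs of the target-drug reports (e.g. from
#'   [select_target_reports()]).
#' @param level `"pt"` or `"soc"`.
#' @param min_count Minimum `a` for a table to be emitted; must be >= 1.
#' @param unit Denominator unit, `"report"` (default) or `"pair"`.
#' @return A tibble with columns `term`, `soc`, `a`, `b`, `c`, `d`,
#'   `n` (= `a`) and `expected` (`(a+b)(a+c)/N`).
#' @export
build_contingency <- function(reports, reactions, target_ids,
                              level = c("pt", "soc"), min_count = 5,
                              unit = c("report", "pair")) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  if (!is.numeric(min_count) || min_count < 1) {
    stop_config("`min_count` must be >= 1")
  }
  if (level == "soc" && !"soc" %in% names(reactions)) {
    stop_config("`reactions` must carry a `soc` column at SOC level; run map_pts() first")
  }

  term_col <- if (level == "pt") "pt" else "soc"
  rx <- reactions |>
    dplyr::semi_join(reports, by = dplyr::join_by("primaryid" == "primaryid")) |>
    dplyr::mutate(term = .data[[term_col]]) |>
    dplyr::distinct(.data$primaryid, .data$term)
  rx$is_target <- rx$primaryid %in% target_ids

  n_target <- sum(reports$primaryid %in% target_ids)
  n_other <- nrow(reports) - n_target
  if (unit == "pair") {
    n_target <- sum(rx$is_target)
    n_other <- nrow(rx) - n_target
  }

  counts <- rx |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      a = sum(.data$is_target),
      c = sum(!.data$is_target),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$a >= min_count) |>
    dplyr::mutate(
      b = n_target - .data$a,
      d = n_other - .data$c,
      n = .data$a
    )

  if (level == "pt" && "soc" %in% names(reactions)) {
    soc_of <- reactions |>
      dplyr::distinct(.data$pt, .data$soc) |>
      dplyr::group_by(.data$pt) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    counts <- dplyr::left_join(counts, soc_of,
                               by = dplyr::join_by("term" == "pt"))
  } else if (level == "soc") {
    counts$soc <- counts$term
  } else {
    counts$soc <- NA_character_
  }

  counts |>
    dplyr::mutate(
      expected = (.data$a + .data$b) * (.data$a + .data$c) /
        (.data$a + .data$b + .data$c + .data$d)
    ) |>
    dplyr::select("term", "soc", "a", "b", "c", "d", "n", "expected") |>
    dplyr::arrange(dplyr::desc(.data$a), .data$term)
}
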