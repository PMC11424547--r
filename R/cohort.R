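# Descriptive and comparative cohort statistics for the target-drug
# report set: demographics, time-to-onset, serious vs non-serious
# contrasts, pediatric-vs-adult subgroup disproportionality.

ONSET_BIN_LEVELS <- c("0-30", "31-60", "61-90", "91-180", "181-360", ">360")

#' Demographic summary of a report set
#'
#' Counts and percentages by sex, age group, reporter occupation,
#' occurrence country, outcome code and reporting year, in the layout of
#' published baseline tables. Percentages are computed against the total
#' report count and rounded half-up to two decimals; outcome rows
#' additionally report the percentage against the total number of outcome
#' entries, because a report can carry several outcome codes and published
#' tables are ambiguous about the denominator. Each row names its
#' denominator explicitly.
#'
#' @param reports Deduplicated report tibble.
#' @param top_countries Number of individual countries listed before
#'   collapsing the rest into `"Other"`.
#' @return A tibble with columns `section`, `category`, `n`,
#'   `pct_of_reports`, `pct_of_entries` (outcome rows only),
#'   `denominator_reports`, `denominator_entries`.
#' @export
demographic_summary <- function(reports, top_countries = 5) {
  n_total <- nrow(reports)
  block <- function(section, x) {
    tibble::tibble(category = x) |>
      dplyr::count(.data$category, name = "n") |>
      dplyr::mutate(section = section, .before = 1)
  }

  country <- as.character(ifelse(is.na(reports$country), "Unknown",
                                 reports$country))
  main <- names(sort(table(country[country != "Unknown"]),
                     decreasing = TRUE))
  main <- head(main, top_countries)
  country_grp <- as.character(ifelse(country %in% c(main, "Unknown"),
                                     country, "Other"))

  outcome_entries <- unlist(reports$outcomes, use.names = FALSE)
  n_entries <- length(outcome_entries)

  out <- dplyr::bind_rows(
    block("sex", reports$sex),
    block("age_group",
          factor(reports$age_group, levels = AGE_GROUP_LEVELS) |>
            as.character()),
    block("reporter", reports$reporter),
    block("country", country_grp),
    block("year", as.character(reports$year)),
    if (n_entries) block("outcome", outcome_entries) else NULL
  ) |>
    dplyr::mutate(
      pct_of_reports = pct2(.data$n, n_total),
      pct_of_entries = ifelse(.data$section == "outcome",
                              pct2(.data$n, max(n_entries, 1)), NA_real_),
      denominator_reports = n_total,
      denominator_entries = ifelse(.data$section == "outcome",
                                   n_entries, NA_integer_)
    )
  if (n_total == 0) out <- out[0, ]
  out
}

#' Time-to-onset records for target-drug reports
#'
#' Onset is the difference in days between the adverse-event date and the
#' earliest therapy start date over the report's primary-suspect drug
#' records; both dates must have day precision. Records with a missing or
#' negative difference are excluded and counted, never silently dropped.
#' Bins follow the conventional strata 0-30, 31-60, 61-90, 91-180,
#' 181-360, >360 days (closed on both ends, the last open above).
#'
#' @param reports Report tibble (target-drug, deduplicated).
#' @param drugs Drug-record tibble with `role` and `start_date`.
#' @return A tibble of onset records (`primaryid`, `onset_days`, `bin`)
#'   with exclusion counters in `attr(, "exclusions")` (named integer:
#'   `missing`, `negative`).
#' @export
onset_records <- function(reports, drugs) {
  starts <- drugs |>
    dplyr::filter(.data$role == "PS", !is.na(.data$start_date)) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(start_date = min(.data$start_date), .groups = "drop")

  joined <- reports |>
    dplyr::select("primaryid", "event_date") |>
    dplyr::left_join(starts, by = dplyr::join_by("primaryid" == "primaryid")) |>
    dplyr::mutate(onset_days = as.numeric(.data$event_date - .data$start_date))

  n_missing <- sum(is.na(joined$onset_days))
  n_negative <- sum(!is.na(joined$onset_days) & joined$onset_days < 0)
  out <- joined |>
    dplyr::filter(!is.na(.data$onset_days), .data$onset_days >= 0) |>
    dplyr::mutate(
      onset_days = as.integer(.data$onset_days),
      bin = onset_bin_of(.data$onset_days)
    ) |>
    dplyr::select("primaryid", "onset_days", "bin")
  attr(out, "exclusions") <- c(missing = n_missing, negative = n_negative)
  out
}

onset_bin_of <- function(days) {
  dplyr::case_when(
    days <= 30 ~ "0-30",
    days <= 60 ~ "31-60",
    days <= 90 ~ "61-90",
    days <= 180 ~ "91-180",
    days <= 360 ~ "181-360",
    TRUE ~ ">360"
  )
}

#' Summarise time-to-onset
#'
#' Median and interquartile range by linear interpolation (quantile
#' type 7), plus per-bin counts and percentages over the reports with a
#' computable onset (the denominator is emergent from the data, not the
#' report total).
#'
#' @param onset Output of [onset_records()].
#' @return A list with `summary` (one-row tibble: `n`, `median_days`,
#'   `q1_days`, `q3_days`) and `bins` (tibble `bin`, `n`, `pct`).
#' @export
onset_summary <- function(onset) {
  n_tot <- nrow(onset)
  summary <- tibble::tibble(
    n = n_tot,
    median_days = if (n_tot) median(onset$onset_days) else NA_real_,
    q1_days = if (n_tot) unname(quantile(onset$onset_days, 0.25, type = 7))
              else NA_real_,
    q3_days = if (n_tot) unname(quantile(onset$onset_days, 0.75, type = 7))
              else NA_real_
  )
  bins <- tibble::tibble(bin = factor(onset$bin, levels = ONSET_BIN_LEVELS)) |>
    dplyr::count(.data$bin, .drop = FALSE, name = "n") |>
    dplyr::mutate(bin = as.character(.data$bin),
                  pct = pct2(.data$n, n_tot))
  list(summary = summary, bins = bins)
}

# Pearson chi-squared on an r x c count matrix; flags low expected cells.
contrast_test <- function(mat) {
  keep <- rowSums(mat) > 0
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 2 || any(colSums(mat) == 0)) {
    return(list(chi2 = NA_real_, p = NA_real_, low_expected = NA))
  }
  tst <- suppressWarnings(chisq.test(mat, correct = FALSE))
  list(chi2 = unname(tst$statistic), p = unname(tst$p.value),
       low_expected = any(tst$expected < 5))
}

#' Serious versus non-serious report contrasts
#'
#' Splits the target-drug reports by the serious flag (death,
#' life-threatening, hospitalisation, disability) and contrasts the two
#' groups on gender, age group, and presence of each of the `top_k` most
#' frequent preferred terms, with column percentages and a two-sided
#' Pearson chi-squared p-value per block or term (no continuity
#' correction; the degrees of freedom follow the table shape). Tables with
#' an expected cell below 5 are flagged, not suppressed.
#'
#' @param reports Target-drug report tibble.
#' @param reactions Reaction tibble for the same reports.
#' @param top_k Number of most-reported PTs to contrast.
#' @param sig_level Significance label threshold (default 0.001, the
#'   convention of published serious/non-serious tables).
#' @return A tibble with columns `block`, `category`, `serious_n`,
#'   `serious_pct`, `nonserious_n`, `nonserious_pct`, `chi2`, `p_value`,
#'   `low_expected`, `significant`.
#' @export
serious_contrast <- function(reports, reactions, top_k = 30,
                             sig_level = 0.001) {
  n_serious <- sum(reports$serious)
  n_nonserious <- sum(!reports$serious)

  cat_block <- function(block, x) {
    lv <- unique(x[!is.na(x) & x != "unknown"])
    mat <- vapply(c(TRUE, FALSE), function(s) {
      vapply(lv, function(l) {
        sum(!is.na(x) & x == l & reports$serious == s)
      }, integer(1))
    }, integer(length(lv)))
    if (length(lv) == 1) mat <- matrix(mat, nrow = 1)
    tst <- contrast_test(mat)
    tibble::tibble(
      block = block, category = lv,
      serious_n = unname(mat[, 1]), nonserious_n = unname(mat[, 2]),
      serious_pct = unname(pct2(mat[, 1], sum(mat[, 1]))),
      nonserious_pct = unname(pct2(mat[, 2], sum(mat[, 2]))),
      chi2 = tst$chi2, p_value = tst$p, low_expected = tst$low_expected
    )
  }

  blocks <- dplyr::bind_rows(
    cat_block("gender", reports$sex),
    cat_block("age_group", ifelse(reports$age_group == "unknown",
                                  NA_character_, reports$age_group))
  )

  rx <- reactions |>
    dplyr::semi_join(reports, by = dplyr::join_by("primaryid" == "primaryid")) |>
    dplyr::distinct(.data$primaryid, .data$pt)
  top_terms <- rx |>
    dplyr::count(.data$pt, sort = TRUE, name = "n_reports") |>
    head(top_k)

  serious_ids <- reports$primaryid[reports$serious]
  nonserious_ids <- reports$primaryid[!reports$serious]
  term_rows <- purrr::map_dfr(top_terms$pt, function(term) {
    with_term <- rx$primaryid[rx$pt == term]
    s1 <- length(intersect(with_term, serious_ids))
    n1 <- length(intersect(with_term, nonserious_ids))
    mat <- matrix(c(s1, n_serious - s1, n1, n_nonserious - n1), nrow = 2)
    tst <- contrast_test(mat)
    tibble::tibble(
      block = "pt", category = term,
      serious_n = s1, nonserious_n = n1,
      serious_pct = pct2(s1, n_serious),
      nonserious_pct = pct2(n1, n_nonserious),
      chi2 = tst$chi2, p_value = tst$p, low_expected = tst$low_expected
    )
  })

  dplyr::bind_rows(blocks, term_rows) |>
    dplyr::mutate(significant = !is.na(.data$p_value) &
                    .data$p_value < sig_level)
}

#' Pediatric versus adult within-drug disproportionality
#'
#' Within the target-drug reports with known age, each term's 2x2 table of
#' (pediatric vs adult) x (term vs not) is scored with the same
#' reporting-odds-ratio closed form as the drug-level analysis. A lower CI
#' bound above 1 marks the term pediatric-enriched; an upper bound below 1
#' marks it adult-enriched. Swapping the subgroups returns the reciprocal
#' ROR.
#'
#' @param reports Target-drug report tibble.
#' @param reactions Reaction tibble.
#' @param cutoff_age Pediatric cutoff in years (default < 18).
#' @param min_count Minimum pediatric report count per term.
#' @param correction Haldane-Anscombe +0.5 on zero-cell tables.
#' @return Tibble with `term`, pediatric/adult with/without counts,
#'   `n` (pediatric with-term count), `ror`, `ror_lo`, `ror_hi`,
#'   `direction` (`"pediatric"`, `"adult"`, `"indeterminate"`).
#' @export
subgroup_disprop <- function(reports, reactions, cutoff_age = 18,
                             min_count = 5, correction = TRUE) {
  known <- dplyr::filter(reports, !is.na(.data$age_years))
  known$pediatric <- known$age_years < cutoff_age
  rx <- reactions |>
    dplyr::semi_join(known, by = dplyr::join_by("primaryid" == "primaryid")) |>
    dplyr::distinct(.data$primaryid, .data$pt)
  rx$pediatric <- rx$primaryid %in% known$primaryid[known$pediatric]

  n_ped <- sum(known$pediatric)
  n_adult <- nrow(known) - n_ped

  counts <- rx |>
    dplyr::group_by(.data$pt) |>
    dplyr::summarise(
      ped_with = sum(.data$pediatric),
      adult_with = sum(!.data$pediatric),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$ped_with + .data$adult_with >= min_count) |>
    dplyr::mutate(
      ped_without = n_ped - .data$ped_with,
      adult_without = n_adult - .data$adult_with
    )
  if (!nrow(counts)) {
    return(tibble::tibble(
      term = character(), ped_with = integer(), ped_without = integer(),
      adult_with = integer(), adult_without = integer(), n = integer(),
      ror = numeric(), ror_lo = numeric(), ror_hi = numeric(),
      direction = character()
    ))
  }
  r <- ror_stats(counts$ped_with, counts$ped_without,
                 counts$adult_with, counts$adult_without,
                 correction = correction)
  # an empty subgroup margin leaves the odds ratio undefined even with the
  # continuity correction
  if (n_ped == 0 || n_adult == 0) r[] <- NA_real_
  dplyr::bind_cols(
    dplyr::rename(counts, term = "pt"),
    tibble::tibble(n = counts$ped_with), r
  ) |>
    dplyr::mutate(direction = dplyr::case_when(
      is.na(.data$ror_lo) ~ "indeterminate",
      .data$ror_lo > 1 ~ "pediatric",
      .data$ror_hi < 1 ~ "adult",
      TRUE ~ "indeterminate"
    )) |>
    dplyr::arrange(dplyr::desc(.data$n))
}
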