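#' Compute all four disproportionality statistics per term
#'
#' Takes a contingency tibble and appends the full score set used in
#' published FAERS signal tables: ROR with 95% CI, PRR with 95% CI,
#' the Pearson chi-squared statistic with raw and Bonferroni-adjusted
#' p-values, the BCPNN information component with its lower credibility
#' bound, and the MGPS EBGM with its 5th posterior percentile. The MGPS
#' prior is fitted across all supplied tables unless one is passed in.
#'
#' @param tables Contingency tibble from [build_contingency()].
#' @param correction Haldane-Anscombe +0.5 on zero-cell tables for
#'   ROR/PRR.
#' @param yates Yates-corrected chi-squared variant.
#' @param bcpnn BCPNN priors, see [bcpnn_priors()].
#' @param prior Optional pre-fitted [fit_mgps()] prior; fitted from
#'   `tables` when `NULL`.
#' @param m Number of tests for the Bonferroni adjustment; defaults to the
#'   number of supplied tables.
#' @return A `disprop_scores` tibble: the input columns plus `ror`,
#'   `ror_lo`, `ror_hi`, `prr`, `prr_lo`, `prr_hi`, `chi2`, `ic`, `ic025`,
#'   `ebgm`, `ebgm05`, `p_value`, `adjusted_p`. The fitted prior is
#'   attached as `attr(, "prior")`.
#' @examples
#' ct <- tibble::tibble(
#'   term = c("t1", "t2"), soc = NA_character_,
#'   a = c(20, 6), b = c(80, 94), c = c(100, 150), d = c(9800, 9750),
#'   n = c(20, 6), expected = NA
#' )
#' ct$expected <- with(ct, (a + b) * (a + c) / (a + b + c + d))
#' disprop_scores(ct)
#' @export
disprop_scores <- function(tables, correction = TRUE, yates = FALSE,
                           bcpnn = bcpnn_priors(), prior = NULL, m = NULL) {
  if (!nrow(tables)) {
    stop_config("no contingency tables supplied")
  }
  if (is.null(prior) && nrow(tables) >= 2) {
    prior <- fit_mgps(tables)
  }
  r <- ror_stats(tables$a, tables$b, tables$c, tables$d,
                 correction = correction)
  p <- prr_stats(tables$a, tables$b, tables$c, tables$d,
                 correction = correction, yates = yates)
  b <- bcpnn_stats(tables$a, tables$b, tables$c, tables$d, priors = bcpnn)
  eb <- if (!is.null(prior)) {
    ebgm_stats(tables$a, tables$expected, prior)
  } else {
    tibble::tibble(ebgm = rep(NA_real_, nrow(tables)),
                   ebgm05 = NA_real_)
  }
  m <- m %||% nrow(tables)
  out <- dplyr::bind_cols(
    tables, r,
    dplyr::select(p, "prr", "prr_lo", "prr_hi", "chi2"),
    dplyr::select(b, "ic", "ic025"), eb,
    tibble::tibble(p_value = p$p_value,
                   adjusted_p = bonferroni(p$p_value, m = m))
  )
  attr(out, "prior") <- prior
  class(out) <- c("disprop_scores", class(out))
  out
}
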