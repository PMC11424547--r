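# Closed-form disproportionality statistics on 2x2 tables.
#
# All functions are vectorised over table cells and return tibbles, so they
# compose with the contingency builder via mutate(). Cells that make a
# statistic undefined (zero cells / margins with the continuity correction
# disabled) yield NA rather than an error; screening downstream treats NA
# as an "undefined" verdict.

# apply the Haldane-Anscombe +0.5 to all four cells of tables with any zero
haldane <- function(a, b, c, d, correction) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  add <- ifelse(correction & zero, 0.5, 0)
  list(a = a + add, b = b + add, c = c + add, d = d + add)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a d) / (b c)` with the log-normal (Woolf) interval
#' `exp(log ROR -/+ 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero a Haldane-Anscombe +0.5 correction is applied to all four cells
#' (default); with `correction = FALSE` such tables return `NA` (an
#' undefined-statistic flag, not an error).
#'
#' @param a,b,c,d Cell counts: target-drug reports with/without the term,
#'   other reports with/without the term. Vectorised.
#' @param correction Apply the +0.5 continuity correction to zero-cell
#'   tables.
#' @param conf_level Confidence level of the interval.
#' @return Tibble with columns `ror`, `ror_lo`, `ror_hi`.
#' @examples
#' ror_stats(10, 90, 100, 9800)
#' @export
ror_stats <- function(a, b, c, d, correction = TRUE, conf_level = 0.95) {
  h <- haldane(a, b, c, d, correction)
  ok <- h$a > 0 & h$b > 0 & h$c > 0 & h$d > 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- ifelse(ok, (h$a * h$d) / (h$b * h$c), NA_real_)
  se <- ifelse(ok, sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d), NA_real_)
  tibble::tibble(
    ror = est,
    ror_lo = exp(log(est) - z * se),
    ror_hi = exp(log(est) + z * se)
  )
}

#' Pearson chi-squared statistic for a 2x2 table
#'
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on one degree of freedom, with
#' the Yates continuity correction behind a flag.
#'
#' @inheritParams ror_stats
#' @param yates Apply the Yates correction (subtract N/2 from |ad - bc|).
#' @return Numeric vector of chi-squared statistics (NA on a zero margin).
#' @export
pearson_chi2 <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(0, num - n / 2)
  ifelse(denom > 0, n * num^2 / denom, NA_real_)
}

#' Proportional reporting ratio, interval and chi-squared test
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with interval
#' `exp(log PRR -/+ 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`, reported
#' together with the Pearson chi-squared statistic (df = 1) and its
#' two-sided p-value.
#'
#' @inheritParams ror_stats
#' @param yates Use the Yates-corrected chi-squared variant.
#' @return Tibble with columns `prr`, `prr_lo`, `prr_hi`, `chi2`,
#'   `p_value`.
#' @examples
#' prr_stats(10, 90, 100, 9800)
#' @export
prr_stats <- function(a, b, c, d, correction = TRUE, yates = FALSE,
                      conf_level = 0.95) {
  h <- haldane(a, b, c, d, correction)
  ok <- h$a > 0 & h$c > 0 & (h$a + h$b) > 0 & (h$c + h$d) > 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- ifelse(ok, (h$a / (h$a + h$b)) / (h$c / (h$c + h$d)), NA_real_)
  se <- ifelse(ok, sqrt(pmax(0, 1 / h$a - 1 / (h$a + h$b) +
                               1 / h$c - 1 / (h$c + h$d))), NA_real_)
  chi2 <- pearson_chi2(a, b, c, d, yates = yates)
  tibble::tibble(
    prr = est,
    prr_lo = exp(log(est) - z * se),
    prr_hi = exp(log(est) + z * se),
    chi2 = chi2,
    p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  )
}

#' Prior pseudo-counts for the BCPNN information component
#'
#' The standard closed-form BCPNN places Beta/Dirichlet-style priors on the
#' joint and marginal reporting probabilities. Defaults are the cited
#' convention: marginal pseudo-counts 1, joint pseudo-count 1, prior totals
#' 2, and an interval multiplier of 2 standard deviations (1.96 selectable)
#' for the lower bound.
#'
#' @param alpha1_m,beta1_m Marginal pseudo-counts (default 1).
#' @param alpha,beta Prior totals for the margins (default 2).
#' @param gamma11 Joint pseudo-count (default 1).
#' @param k Interval multiplier: `ic025 = E(IC) - k sqrt(V(IC))`.
#' @return A `bcpnn_priors` list.
#' @export
bcpnn_priors <- function(alpha1_m = 1, beta1_m = 1, alpha = 2, beta = 2,
                         gamma11 = 1, k = 2) {
  vals <- c(alpha1_m, beta1_m, alpha, beta, gamma11, k)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_config("BCPNN priors must all be positive")
  }
  structure(list(alpha1_m = alpha1_m, beta1_m = beta1_m, alpha = alpha,
                 beta = beta, gamma11 = gamma11, k = k),
            class = "bcpnn_priors")
}

#' BCPNN information component with credibility bound
#'
#' Closed-form posterior expectation and variance of the information
#' component `IC = log2 p11 / (p1. p.1)`:
#'
#' `E(IC) = log2[(a + g11)(N + alpha)(N + beta) /
#'               ((N + g)(a + b + a1)(a + c + b1))]`
#'
#' with `g = g11 (N + alpha)(N + beta) / ((a + b + a1)(a + c + b1))`, and
#'
#' `V(IC) = [ (N - a + g - g11) / ((a + g11)(1 + N + g))
#'          + (N - (a+b) + alpha - a1) / ((a + b + a1)(1 + N + alpha))
#'          + (N - (a+c) + beta - b1) / ((a + c + b1)(1 + N + beta)) ]
#'          / (log 2)^2`.
#'
#' `ic025 = E(IC) - k sqrt(V(IC))`. A Monte-Carlo variant
#' (`method = "mc"`) samples the posterior Beta distributions of the joint
#' and marginal probabilities directly and agrees with the closed form
#' within Monte-Carlo error.
#'
#' @inheritParams ror_stats
#' @param priors A [bcpnn_priors()] object.
#' @param method `"closed"` (default) or `"mc"`.
#' @param n_mc Number of Monte-Carlo samples when `method = "mc"`.
#' @return Tibble with columns `ic`, `ic_var`, `ic025`.
#' @export
bcpnn_stats <- function(a, b, c, d, priors = bcpnn_priors(),
                        method = c("closed", "mc"), n_mc = 100000) {
  method <- match.arg(method)
  stopifnot(inherits(priors, "bcpnn_priors"))
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  a1 <- priors$alpha1_m
  b1 <- priors$beta1_m
  al <- priors$alpha
  be <- priors$beta
  g11 <- priors$gamma11

  if (method == "mc") {
    stopifnot(length(a) == 1)
    g <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
    p11 <- rbeta(n_mc, a + g11, n - a + g - g11)
    p1 <- rbeta(n_mc, a + b + a1, n - (a + b) + al - a1)
    p2 <- rbeta(n_mc, a + c + b1, n - (a + c) + be - b1)
    ic_draws <- log2(p11 / (p1 * p2))
    return(tibble::tibble(
      ic = mean(ic_draws),
      ic_var = stats::var(ic_draws),
      ic025 = mean(ic_draws) - priors$k * stats::sd(ic_draws)
    ))
  }

  g <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  e_ic <- log2((a + g11) * (n + al) * (n + be) /
                 ((n + g) * (a + b + a1) * (a + c + b1)))
  v_ic <- ((n - a + g - g11) / ((a + g11) * (1 + n + g)) +
             (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
             (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be))) /
    log(2)^2
  tibble::tibble(ic = e_ic, ic_var = v_ic,
                 ic025 = e_ic - priors$k * sqrt(v_ic))
}

#' Maximum-likelihood information component
#'
#' The prior-free point estimate `log2( a N / ((a+b)(a+c)) )`, i.e. the
#' log2 ratio of the observed count to its expectation under independence.
#' Returns NA when a margin or `a` is zero.
#'
#' @inheritParams ror_stats
#' @return Numeric vector.
#' @export
ml_ic <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  ok <- a > 0 & (a + b) > 0 & (a + c) > 0
  ifelse(ok, log2(a * n / ((a + b) * (a + c))), NA_real_)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` with `m` the number of tests — by convention the number
#' of terms passing the minimum-count rule at the screened level. Thin
#' wrapper over [stats::p.adjust()] so ordering is preserved.
#'
#' @param p Numeric vector of p-values.
#' @param m Number of tests; defaults to `length(p)`.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) {
  stats::p.adjust(p, method = "bonferroni", n = m)
}
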