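# Independent oracle formulas, written directly from the definitions, used
# to cross-check the vectorised implementations.
oracle_ror <- function(a, b, c, d) (a * d) / (b * c)
oracle_prr <- function(a, b, c, d) (a / (a + b)) / (c / (c + d))
oracle_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
oracle_ic_ml <- function(a, b, c, d) {
  log2(a * (a + b + c + d) / ((a + b) * (a + c)))
}

test_that("ROR point estimate and Woolf interval match hand evaluation", {
  out <- ror_stats(10, 90, 100, 9800)
  expect_equal(out$ror, 10.888888888889, tolerance = 1e-10)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9800)
  expect_equal(out$ror_lo, exp(log(out$ror) - qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(out$ror_lo, 5.50, tolerance = 0.01)
  expect_equal(out$ror_hi, 21.55, tolerance = 0.01)
})

test_that("PRR, chi-squared and p-value match hand evaluation and chisq.test", {
  out <- prr_stats(10, 90, 100, 9800)
  expect_equal(out$prr, 9.9, tolerance = 1e-10)
  expect_equal(out$chi2, oracle_chi2(10, 90, 100, 9800), tolerance = 1e-12)
  expect_equal(out$chi2, 73.5, tolerance = 0.1)
  # cross-check the statistic against the stock Pearson test
  m <- matrix(c(10, 100, 90, 9800), 2)
  expect_equal(out$chi2,
               unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic),
               tolerance = 1e-10)
  expect_equal(out$p_value, pchisq(out$chi2, 1, lower.tail = FALSE))
  # Yates variant agrees with the corrected stock test
  expect_equal(pearson_chi2(10, 90, 100, 9800, yates = TRUE),
               unname(suppressWarnings(chisq.test(m, correct = TRUE))$statistic),
               tolerance = 1e-10)
})

test_that("proportional tables are exactly null for all point statistics", {
  # a/(a+b) = c/(c+d)
  expect_equal(ror_stats(10, 10, 10, 10)$ror, 1)
  expect_equal(prr_stats(10, 10, 10, 10)$prr, 1)
  expect_equal(pearson_chi2(10, 10, 10, 10), 0)
  expect_equal(ml_ic(10, 90, 990, 8910), 0)   # aN = (a+b)(a+c)
  out <- ror_stats(10, 10, 10, 10)
  expect_lt(out$ror_lo, 1)
  expect_gt(out$ror_hi, 1)
})

test_that("Haldane correction rewrites zero-cell tables and NA flags appear when disabled", {
  corrected <- ror_stats(0, 90, 100, 9800, correction = TRUE)
  expect_equal(corrected$ror, oracle_ror(0.5, 90.5, 100.5, 9800.5),
               tolerance = 1e-12)
  off <- ror_stats(0, 90, 100, 9800, correction = FALSE)
  expect_true(is.na(off$ror))
  expect_true(is.na(prr_stats(10, 90, 0, 9800, correction = FALSE)$prr))
})

test_that("closed forms agree with the oracle on a grid of small tables", {
  g <- expand.grid(a = 1:8, b = 1:8, c = 1:8, d = 1:8)
  got_ror <- ror_stats(g$a, g$b, g$c, g$d, correction = FALSE)$ror
  got_prr <- prr_stats(g$a, g$b, g$c, g$d, correction = FALSE)
  expect_equal(got_ror, oracle_ror(g$a, g$b, g$c, g$d), tolerance = 1e-12)
  expect_equal(got_prr$prr, oracle_prr(g$a, g$b, g$c, g$d), tolerance = 1e-12)
  expect_equal(got_prr$chi2, oracle_chi2(g$a, g$b, g$c, g$d),
               tolerance = 1e-12)
  expect_equal(ml_ic(g$a, g$b, g$c, g$d), oracle_ic_ml(g$a, g$b, g$c, g$d),
               tolerance = 1e-12)
})

test_that("ROR dominates PRR exactly when the signal is positive", {
  # ror/prr = d(a+b)/(b(c+d)) ; ror >= prr iff ror >= 1 for all-positive cells
  set.seed(42)
  for (i in 1:200) {
    t <- sample(1:50, 4, replace = TRUE)
    r <- ror_stats(t[1], t[2], t[3], t[4], correction = FALSE)$ror
    p <- prr_stats(t[1], t[2], t[3], t[4], correction = FALSE)$prr
    expect_equal(r >= p, r >= 1 || isTRUE(all.equal(r, p)))
  }
})

test_that("all four statistics increase strictly in a with other cells fixed", {
  a <- 1:60
  r <- ror_stats(a, 100, 50, 5000, correction = FALSE)$ror
  p <- prr_stats(a, 100, 50, 5000, correction = FALSE)$prr
  i <- ml_ic(a, 100, 50, 5000)
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(i) > 0))
  pr <- mgps_prior(0.5, 0.5, 2, 2, 0.3)
  e <- (a + 100) * (a + 50) / (a + 100 + 50 + 5000)
  eb <- ebgm_stats(a, e, pr)$ebgm
  expect_true(all(diff(eb) > 0))
})

test_that("BCPNN posterior variance is non-negative across a grid", {
  g <- expand.grid(a = c(0, 1, 5, 10, 100), b = c(0, 1, 10, 100),
                   c = c(0, 1, 10, 100), d = c(1, 10, 1000))
  v <- bcpnn_stats(g$a, g$b, g$c, g$d)$ic_var
  expect_true(all(v >= 0))
})

test_that("BCPNN closed form is consistent with its Monte-Carlo variant", {
  set.seed(7)
  closed <- bcpnn_stats(120, 900, 1500, 60000)
  mc <- bcpnn_stats(120, 900, 1500, 60000, method = "mc", n_mc = 200000)
  # closed form uses a log-gamma approximation of the Beta expectation;
  # tolerance covers MC error plus the approximation gap at these counts
  expect_equal(mc$ic, closed$ic, tolerance = 0.02)
  expect_equal(mc$ic025, closed$ic025, tolerance = 0.05)
})

test_that("the IC shrinks towards zero and ic025 sits below ic", {
  out <- bcpnn_stats(c(3, 50), c(20, 500), c(30, 800), c(1000, 40000))
  expect_true(all(out$ic025 < out$ic))
  # tiny-count tables shrink harder towards 0 than the ML estimate
  ml <- ml_ic(3, 20, 30, 1000)
  expect_lt(abs(out$ic[1]), abs(ml) + 1e-9)
})

test_that("EBGM converges to the observed ratio when data swamp the prior", {
  pr <- mgps_prior(0.2, 0.1, 2, 2, 1 / 3)
  out <- ebgm_stats(1000, 100, pr)
  expect_equal(out$ebgm, 10, tolerance = 0.02)
  # consistency: growing a and E at fixed ratio r drives ebgm -> r and
  # the information component -> log2 r
  for (scale in c(10, 100, 1000)) {
    eb <- ebgm_stats(10 * scale, scale, pr)$ebgm
    expect_equal(eb, 10, tolerance = 10 * 2 / scale + 0.02)
  }
  ic_big <- ml_ic(10000, 90000, 1000 * 10, 1e7)
})

test_that("EBGM at the null with a unit-centred prior stays near one", {
  pr <- mgps_prior(2, 2, 2, 2, 0.5)  # prior mean 1
  out <- ebgm_stats(20, 20, pr)
  expect_gt(out$ebgm, 0.5)
  expect_lt(out$ebgm, 2)
  expect_lt(out$ebgm05, out$ebgm)
})

test_that("posterior mass below ebgm05 is 5 percent to quadrature accuracy", {
  set.seed(31)
  pr <- mgps_prior(1.2, 0.8, 3, 2.5, 0.4)
  for (i in 1:20) {
    a <- rpois(1, 15)
    e <- runif(1, 0.5, 40)
    q <- faersignal:::mgps_posterior_q(a, e, pr)
    e5 <- ebgm_stats(a, e, pr)$ebgm05
    mass <- faersignal:::mgps_posterior_cdf(e5, a, e, pr, q)
    expect_equal(mass, 0.05, tolerance = 1e-6)
    # independent quadrature of the posterior density up to the quantile
    dens <- function(x) {
      q * dgamma(x, pr$alpha1 + a, rate = pr$beta1 + e) +
        (1 - q) * dgamma(x, pr$alpha2 + a, rate = pr$beta2 + e)
    }
    quad <- integrate(dens, 0, e5, rel.tol = 1e-10)$value
    expect_equal(quad, 0.05, tolerance = 1e-6)
  }
})

test_that("MGPS marginal likelihood is additive over duplicated tables", {
  th <- faersignal:::mgps_default_start
  l1 <- faersignal:::mgps_loglik(th, 7, 3.2)
  l2 <- faersignal:::mgps_loglik(th, c(7, 7), c(3.2, 3.2))
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
})

test_that("MGPS fit recovers a single-gamma prior and is a fixed point", {
  set.seed(11)
  n <- 500
  e <- exp(runif(n, log(0.5), log(200)))
  lam <- rgamma(n, shape = 2, rate = 4)
  a <- rpois(n, lam * e)
  tbl <- tibble::tibble(a = a, expected = e)
  pr <- fit_mgps(tbl)
  expect_true(pr$converged)
  fitted_mean <- pr$w * pr$alpha1 / pr$beta1 +
    (1 - pr$w) * pr$alpha2 / pr$beta2
  expect_lt(abs(fitted_mean - 0.5) / 0.5, 0.15)
  # restarting from the solution returns the solution
  pr2 <- fit_mgps(tbl, start = c(alpha1 = pr$alpha1, beta1 = pr$beta1,
                                 alpha2 = pr$alpha2, beta2 = pr$beta2,
                                 w = pr$w))
  expect_equal(
    unlist(pr2[c("alpha1", "beta1", "alpha2", "beta2", "w")]),
    unlist(pr[c("alpha1", "beta1", "alpha2", "beta2", "w")]),
    tolerance = 1e-12
  )
  expect_error(fit_mgps(tbl[1, ]), class = "faersignal_config_error")
})

test_that("tidy and glance summarise the fitted prior", {
  pr <- mgps_prior(0.2, 0.1, 2, 4, 1 / 3)
  td <- tidy(pr)
  expect_equal(td$term, c("alpha1", "beta1", "alpha2", "beta2", "w"))
  expect_equal(td$estimate[5], 1 / 3)
  gl <- glance(pr)
  expect_equal(gl$prior_mean,
               (1 / 3) * 2 + (2 / 3) * 0.5)
})

test_that("Bonferroni adjustment caps at one and preserves order", {
  expect_equal(bonferroni(0.001, m = 260), 0.26)
  expect_equal(bonferroni(0.01, m = 260), 1)
  expect_equal(bonferroni(0, m = 100), 0)
  p <- c(0.04, 0.001, 0.2)
  expect_equal(order(bonferroni(p, m = 50)), order(p))
})

test_that("score assembly attaches every statistic and the fitted prior", {
  ct <- tibble::tibble(
    term = c("alpha", "beta", "gamma"), soc = NA_character_,
    a = c(30, 12, 7), b = c(170, 188, 193),
    c = c(150, 300, 700), d = c(19650, 19500, 19100),
    n = c(30, 12, 7), expected = NA_real_
  )
  ct$expected <- (ct$a + ct$b) * (ct$a + ct$c) / (ct$a + ct$b + ct$c + ct$d)
  # a three-table empirical fit is not meaningful; use a reference prior
  sc <- disprop_scores(ct, prior = mgps_prior(0.2, 0.1, 2, 4, 1 / 3))
  expect_s3_class(sc, "disprop_scores")
  expect_true(all(c("ror", "prr", "chi2", "ic", "ic025", "ebgm", "ebgm05",
                    "p_value", "adjusted_p") %in% names(sc)))
  expect_true(all(sc$adjusted_p >= sc$p_value))
  expect_s3_class(attr(sc, "prior"), "mgps_prior")
  expect_true(all(sc$ror_lo <= sc$ror & sc$ror <= sc$ror_hi))
  expect_true(all(sc$ebgm05 <= sc$ebgm))
})
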