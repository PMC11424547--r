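# Multi-item gamma-Poisson shrinker (empirical Bayes EBGM).
#
# Model: for each term i, the observed count a_i is Poisson(lambda_i E_i)
# with E_i the expected count under independence, and lambda_i drawn from
# a two-component gamma mixture prior
#   lambda ~ w Gamma(alpha1, beta1) + (1 - w) Gamma(alpha2, beta2)
# (shape/rate). Marginally a_i is a mixture of negative binomials; the
# hyperparameters are fitted by maximising the marginal likelihood over
# all emitted tables at a level.

mgps_default_start <- c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2.0,
                        beta2 = 4.0, w = 1 / 3)

# marginal log-likelihood of counts a with expectations e under theta
mgps_loglik <- function(theta, a, e) {
  with(as.list(theta), {
    l1 <- dnbinom(a, size = alpha1, prob = beta1 / (beta1 + e), log = TRUE)
    l2 <- dnbinom(a, size = alpha2, prob = beta2 / (beta2 + e), log = TRUE)
    hi <- pmax(l1 + log(w), l2 + log(1 - w))
    lo <- pmin(l1 + log(w), l2 + log(1 - w))
    sum(hi + log1p(exp(lo - hi)))
  })
}

to_unconstrained <- function(theta) {
  c(log(theta[1:4]), stats::qlogis(theta[5]))
}
from_unconstrained <- function(x) {
  setNames(c(exp(x[1:4]), stats::plogis(x[5])),
           c("alpha1", "beta1", "alpha2", "beta2", "w"))
}

#' Fit the MGPS gamma-mixture prior by empirical Bayes
#'
#' Maximises the summed marginal (negative-binomial mixture) log-likelihood
#' of the observed counts over the five hyperparameters
#' `(alpha1, beta1, alpha2, beta2, w)`, starting from the conventional
#' `(0.2, 0.1, 2.0, 4.0, 1/3)`. Optimisation runs on an unconstrained
#' scale (log for the gamma parameters, logit for the weight) with
#' Nelder-Mead followed by a BFGS polish, and is deterministic given the
#' inputs and start. On non-convergence the best-found parameters are
#' returned with `converged = FALSE` and a warning.
#'
#' The fit uses the tables of the screened stratum (one drug against the
#' rest of the database) rather than the all-drug-pair universe of full
#' MGPS practice — the only tables this pipeline constructs.
#'
#' @param tables Contingency tibble from [build_contingency()] (needs
#'   `a` and `expected`), with at least 2 rows.
#' @param start Optional named start vector.
#' @return An object of class `mgps_prior`: hyperparameters, `converged`,
#'   `loglik`, `n_terms`.
#' @seealso [ebgm_stats()], [tidy.mgps_prior()]
#' @export
fit_mgps <- function(tables, start = mgps_default_start) {
  if (nrow(tables) < 2) {
    stop_config("MGPS prior fitting needs at least 2 tables")
  }
  a <- tables$a
  e <- tables$expected
  stopifnot(all(e > 0), all(a >= 0))

  negll <- function(x) {
    th <- from_unconstrained(x)
    if (any(!is.finite(th)) || any(th[1:4] <= 0) ||
        th[5] <= 0 || th[5] >= 1) {
      return(.Machine$double.xmax / 2)
    }
    -mgps_loglik(th, a, e)
  }

  x0 <- to_unconstrained(start)
  f0 <- negll(x0)
  # alternate Nelder-Mead and BFGS until neither improves, so the solution
  # is a fixed point of the optimiser (restarting from it returns it)
  x_cur <- x0
  f_cur <- f0
  converged <- TRUE
  for (round in 1:20) {
    fit1 <- optim(x_cur, negll, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
    fit2 <- optim(fit1$par, negll, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-12))
    cand <- if (fit2$value <= fit1$value) fit2 else fit1
    if (cand$value < f_cur - 1e-6) {
      x_cur <- cand$par
      f_cur <- cand$value
      converged <- cand$convergence == 0
      if (round == 20) converged <- FALSE
    } else {
      break
    }
  }
  if (!converged) {
    warn("MGPS hyperparameter optimisation did not converge; returning best-found parameters")
  }
  theta <- from_unconstrained(x_cur)
  best <- list(value = f_cur)
  structure(
    list(alpha1 = theta[["alpha1"]], beta1 = theta[["beta1"]],
         alpha2 = theta[["alpha2"]], beta2 = theta[["beta2"]],
         w = theta[["w"]], converged = converged,
         loglik = -best$value, n_terms = length(a)),
    class = "mgps_prior"
  )
}

#' Construct an MGPS prior from explicit hyperparameters
#'
#' Useful for scoring with a prior fitted elsewhere or for fixed reference
#' priors in simulations; [fit_mgps()] is the empirical-Bayes route.
#'
#' @param alpha1,beta1,alpha2,beta2 Positive gamma shapes/rates.
#' @param w Mixture weight in (0, 1).
#' @return An `mgps_prior` object (with `converged = NA`, `loglik = NA`).
#' @export
mgps_prior <- function(alpha1, beta1, alpha2, beta2, w) {
  if (any(c(alpha1, beta1, alpha2, beta2) <= 0) || w <= 0 || w >= 1) {
    stop_config("MGPS hyperparameters must be positive with w in (0, 1)")
  }
  structure(
    list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2,
         w = w, converged = NA, loglik = NA_real_, n_terms = NA_integer_),
    class = "mgps_prior"
  )
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("MGPS gamma-mixture prior (empirical Bayes fit)\n")
  cat(sprintf("  component 1: Gamma(shape %.4g, rate %.4g), weight %.3f\n",
              x$alpha1, x$beta1, x$w))
  cat(sprintf("  component 2: Gamma(shape %.4g, rate %.4g), weight %.3f\n",
              x$alpha2, x$beta2, 1 - x$w))
  cat(sprintf("  prior mean %.4g | loglik %.4f on %d terms | converged: %s\n",
              prior_mean(x), x$loglik, x$n_terms, x$converged))
  invisible(x)
}

# prior mean of lambda under the fitted mixture
prior_mean <- function(prior) {
  prior$w * prior$alpha1 / prior$beta1 +
    (1 - prior$w) * prior$alpha2 / prior$beta2
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted MGPS prior
#'
#' @param x An `mgps_prior` object.
#' @param ... Unused.
#' @return One row per hyperparameter with columns `term`, `estimate`.
#' @method tidy mgps_prior
#' @export
tidy.mgps_prior <- function(x, ...) {
  tibble::tibble(
    term = c("alpha1", "beta1", "alpha2", "beta2", "w"),
    estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$w)
  )
}

#' One-row summary of the MGPS fit
#'
#' @param x An `mgps_prior` object.
#' @param ... Unused.
#' @return Tibble with `loglik`, `n_terms`, `converged`, `prior_mean`.
#' @method glance mgps_prior
#' @export
glance.mgps_prior <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, n_terms = x$n_terms,
    converged = x$converged, prior_mean = prior_mean(x)
  )
}

# posterior mixture weight of component 1 given count a and expectation e
mgps_posterior_q <- function(a, e, prior) {
  l1 <- log(prior$w) +
    dnbinom(a, size = prior$alpha1,
            prob = prior$beta1 / (prior$beta1 + e), log = TRUE)
  l2 <- log(1 - prior$w) +
    dnbinom(a, size = prior$alpha2,
            prob = prior$beta2 / (prior$beta2 + e), log = TRUE)
  1 / (1 + exp(l2 - l1))
}

# posterior mixture CDF of lambda | a
mgps_posterior_cdf <- function(x, a, e, prior, q) {
  q * pgamma(x, shape = prior$alpha1 + a, rate = prior$beta1 + e) +
    (1 - q) * pgamma(x, shape = prior$alpha2 + a, rate = prior$beta2 + e)
}

#' Empirical Bayes geometric mean and 5th posterior percentile
#'
#' Given the fitted prior, the posterior of the reporting-rate ratio
#' `lambda` for a term with count `a` and expectation `E` is the gamma
#' mixture `Q Gamma(alpha1 + a, beta1 + E) + (1-Q) Gamma(alpha2 + a,
#' beta2 + E)` with `Q` the posterior component weight. EBGM is the
#' posterior geometric mean `2^{E[log2 lambda]}` (digamma closed form);
#' EBGM05 is the 5th percentile of the posterior mixture, located by
#' bisection on the mixture CDF to `|CDF - 0.05| <= 1e-8`.
#'
#' @param a Observed report counts (vectorised).
#' @param e Expected counts under independence (`E > 0`; a zero expectation
#'   flags the statistic undefined).
#' @param prior A fitted [fit_mgps()] object.
#' @return Tibble with columns `ebgm`, `ebgm05`.
#' @export
ebgm_stats <- function(a, e, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  ok <- e > 0
  q <- mgps_posterior_q(a, e, prior)
  mean_log <- q * (digamma(prior$alpha1 + a) - log(prior$beta1 + e)) +
    (1 - q) * (digamma(prior$alpha2 + a) - log(prior$beta2 + e))
  ebgm <- ifelse(ok, exp(mean_log), NA_real_)

  ebgm05 <- vapply(seq_along(a), function(i) {
    if (!ok[i]) return(NA_real_)
    mixture_quantile(0.05, a[i], e[i], prior, q[i])
  }, numeric(1))

  tibble::tibble(ebgm = ebgm, ebgm05 = ebgm05)
}

# bisection for the p-quantile of the posterior gamma mixture
mixture_quantile <- function(p, a, e, prior, q, tol = 1e-8) {
  lo <- 0
  hi <- max(
    qgamma(1 - 1e-12, shape = prior$alpha1 + a, rate = prior$beta1 + e),
    qgamma(1 - 1e-12, shape = prior$alpha2 + a, rate = prior$beta2 + e)
  )
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    f <- mgps_posterior_cdf(mid, a, e, prior, q)
    if (abs(f - p) <= tol && i > 30) break
    if (f < p) lo <- mid else hi <- mid
  }
  mid
}
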