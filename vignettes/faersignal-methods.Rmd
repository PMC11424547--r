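---
title: "Disproportionality signal detection for spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous-reporting databases such as FAERS collect voluntary reports of
suspected drug–adverse-event pairs. They have no denominator — nobody knows
how many patients took a drug without an event being reported — so
incidence cannot be estimated. What can be estimated is
*disproportionality*: whether a given adverse-event term is reported more
often among one drug's reports than among all other reports. `faersignal`
implements the standard four-algorithm screening workflow used in
published teduglutide-style pharmacovigilance studies: ingestion of the
public quarterly `$`-delimited ASCII tables, two-stage deduplication,
primary-suspect drug selection, report-level 2×2 contingency tables at the
MedDRA preferred-term (PT) and system-organ-class (SOC) levels, four
disproportionality statistics, consensus screening, and descriptive cohort
statistics.

A synthetic spontaneous-report generator with known ground truth
(`sim_config()`, `sim_faers()`) makes the whole pipeline testable without
downloading the real database.

## Counting model

For each term the database is collapsed to the classic 2×2 table against
the rest of the database: `a` target-drug reports with the term, `b`
without it, `c` other-drug reports with the term, `d` without. The
counting unit is the *deduplicated report*: a report contributes at most
one to a cell however many times a term (or, at SOC level, however many of
its PTs) appear on it. Published databases sometimes use drug–reaction
pairs as the denominator instead; `build_contingency(unit = "pair")`
supports that convention, changing only the marginal totals. Tables are
emitted only for terms with `a >= 5` reports, the usual guard against
spurious signals from very rare terms; the Bonferroni adjustment uses the
number of emitted tables at the screened level as the number of tests.

## The four statistics

* **ROR** `= ad/bc`, with the log-normal (Woolf) 95% interval
  `exp(log ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with its analogous interval and the
  Pearson chi-squared statistic
  `N(ad − bc)²/[(a+b)(c+d)(a+c)(b+d)]` on one degree of freedom
  (Yates variant behind a flag; Pearson without correction is the
  default since published signal tables rarely state the variant).
* **BCPNN information component** `IC = log2 p11/(p1·p·1)`, in its
  closed-form posterior expectation and variance under the conventional
  priors (marginal pseudo-counts 1, prior totals 2, joint pseudo-count 1);
  `IC025 = E(IC) − k·√V(IC)` with `k = 2` by default (`1.96` selectable).
  A Monte-Carlo variant samples the posterior Beta distributions directly;
  the closed form is a log-scale approximation of the exact Beta
  expectations, so the two agree closely at moderate counts but not to
  arbitrary precision at very small ones.
* **MGPS EBGM**: each count `a_i` is modelled as Poisson with mean
  `λ_i E_i`, `E_i = (a_i+b_i)(a_i+c_i)/N` the expectation under
  independence, and `λ` drawn from a two-component gamma mixture prior.
  The five hyperparameters are fitted by maximising the marginal
  (negative-binomial mixture) likelihood from the conventional start
  `(0.2, 0.1, 2.0, 4.0, 1/3)`. EBGM is the posterior geometric mean
  `2^{E[log2 λ]}` (digamma closed form); EBGM05 is the 5th posterior
  percentile found by bisection on the posterior-mixture CDF to
  `|ΔCDF| ≤ 1e-8`.

Zero cells make the ratio statistics undefined; the Haldane–Anscombe +0.5
correction (all four cells, only on zero-cell tables) keeps intervals
finite and is on by default. With corrections disabled, undefined
statistics propagate as `NA` and screening counts them as a failed
verdict, recorded in an `undefined` column — missing evidence never argues
*for* a signal.

Two deliberate deviations from full MGPS practice: the prior is fitted
over the tables of the screened stratum (one drug against the rest), not
the all-drug-pair universe, because those are the only tables this
pipeline builds; and the unshrunk ratio `a/E` is available alongside EBGM
for comparison, since published EBGM columns are sometimes
indistinguishable from PRR, suggesting minimal shrinkage in some analyses.

### Optimiser details

The hyperparameter fit runs on an unconstrained scale (log for the gamma
parameters, logit for the weight) alternating Nelder–Mead and BFGS until
neither improves the negative log-likelihood by more than `1e-6`. The
stopping rule makes the fit a fixed point of itself: restarted from its
own solution it returns that solution. On two-cluster or near-degenerate
data the mixture likelihood has flat ridges and the "best" prior may place
very tight components; that is the true maximum-likelihood behaviour on
such data, not a failure, and it is why simulation tests of parameter
recovery use several hundred heterogeneous tables.

## Screening rules

The PT-level consensus rule flags a term only when all four algorithms are
simultaneously positive: lower ROR CI bound > 1; PRR ≥ 2 with χ² ≥ 4;
IC025 > 0; EBGM05 > 2. At SOC level the conjunction is rarely attainable
(SOC aggregates dilute signals), so the customary any-one-of-four rule is
the default there. Ranked outputs mirror the published table shapes: top-k
by report count and top-k by EBGM, the latter additionally filtered to
EBGM05 > 2 (read as a supplementary filter on the consensus survivors).
Ties break by the other key and then term name, so ranking is
deterministic.

## Deduplication

Two stages, in order:

1. **Case-version stage** — FAERS cases are versioned, so only the entry
   with the maximal FDA_DT per CASEID is kept; on ties, the highest
   PRIMARYID. Idempotent.
2. **Key-field stage** — within the target drug's reports, distinct cases
   agreeing on all four of age, sex, country and event date (each
   non-missing) are treated as suspected duplicates; the earliest FDA_DT
   survives, ties broken by lowest PRIMARYID. Reports with any missing key
   are never dropped. Which duplicate to retain is not standardised in the
   literature; earliest-first is this package's documented choice.

## Cohort statistics

Demographic tables report counts and percentages rounded half-up to two
decimals. Because a report can carry several outcome codes, outcome rows
carry two labelled denominators (reports, and outcome entries); published
tables are often ambiguous here, so neither denominator is silently
preferred. Seriousness is derived from the outcome codes: death,
life-threatening, hospitalisation and disability are serious; congenital
anomaly, required intervention and "other" are not by default
(configurable). Time-to-onset is event date minus the earliest
primary-suspect therapy start date, both at day precision; negative or
incomputable onsets are excluded *and counted*. The median and IQR use
linear interpolation (type-7 quantiles). Pediatric-vs-adult contrasts use
the same ROR closed form within the target drug's reports, pediatric
defined as age < 18 completed years.

## The synthetic generator

`sim_faers()` emulates: report demographics (sex, age band with a large
unknown fraction, reporter occupation, country), per-outcome-code
probabilities, a long-tailed lognormal therapy-start-to-event delay
(default median 393 days with quartile ratio ≈ 10, matching the onset
profile of chronic-use drugs), partial dates (`YYYYMM`, `YYYY`) at a
configurable rate, age-unit codes (years/months/days), per-field
missingness, injected duplicates (exact copies except
PRIMARYID/CASEID/FDA_DT), and planted reporting-rate ratios applied
multiplicatively to baseline term probabilities in target-drug reports.
Events falling beyond the 2013–2023Q3 observation window are redrawn
uniformly within it rather than clamped, so no artificial pile-up of
identical event dates forms at the window edge (such an atom would fake
key-field duplicates).

What it does **not** emulate: free-text drug-name noise beyond the
configured synonym variants, multi-drug interaction structure, secular
reporting trends, correlated PT co-occurrence beyond the planted ratios,
and real MedDRA hierarchy (a simplified two-level PT→SOC map stands in for
the licensed dictionary). Passing tests on synthetic data therefore
demonstrate the correctness of the statistical machinery and the
deduplication contracts, not robustness to real-world free-text noise.

## Problem sizes and determinism

The test suite and the acceptance script exercise: a 10⁴-table grid
against independently coded formulas (agreement to 1e-10), EBGM05 against
numerical quadrature on 20 random tables (1e-6), a 10⁴-replicate binomial
null for ROR interval coverage, 500-table prior-recovery simulations, and
20-seed end-to-end runs at 5×10⁴ reports (planted rate ratio 10 on a 2%
baseline) plus 20-seed null runs at 10⁵ reports with 200 terms. These
sizes were chosen so each property is measured with comfortable
Monte-Carlo margin while a full run stays in the minutes range on one
core. Every stochastic step is seeded; identical configuration and seed
give byte-identical output files.

## Known limitations

* No stratified (age/sex/year) Mantel–Haenszel or stratified MGPS; no
  drug–drug interaction (multi-item) shrinkage.
* The BCPNN closed form is an approximation; its MC variant quantifies
  the gap but the closed form is what screening uses, matching field
  practice.
* Bonferroni is the only multiplicity correction, matching the published
  workflow this package mirrors; FDR alternatives are out of scope.
* The printed IC−IC025 spacing in some published tables (≈1.67·√V) matches
  neither the k = 2 nor the k = 1.96 convention; both are offered, k = 2
  being the default.
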