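---
title: "Methods: equity measurement and dual-model workforce forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equity measurement and dual-model workforce forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equicast)
```

## The problem

Health administrations publish annual region-level counts of registered
nurses, doctors, health technicians and hospital beds, together with
resident population and land area. Two questions recur in workforce
planning: *how equitably* is the workforce distributed across regions —
relative to where people live and relative to geography — and *how many*
staff will be needed a few years ahead. `equicast` implements both
analyses over a region-by-year panel, plus a synthetic-panel generator so
every stage is testable without access to the (non-machine-readable)
statistical-yearbook sources such panels usually come from.

## Equity statistics

**Lorenz curve.** For a chosen basis (population or area), regions are
ranked ascending by density (resource per basis unit) and cumulative
basis shares are plotted against cumulative resource shares, from (0,0)
to (1,1). The ranking tie-break is the region label, so results are
reproducible when two regions have identical density.

**Gini coefficient.** Two algebraically equivalent routes are
implemented and cross-checked in the test suite:

* the ranked-share summation `G = 1 - Σ W_i (2V_i - Y_i)` with `W_i` the
  basis share, `Y_i` the resource share and `V_i` the cumulative resource
  share (`gini_paper()`), and
* the geometric definition `G = A/(A+B) = 1 - 2B`, `B` obtained by
  trapezoid integration of the Lorenz polyline (`gini_trapezoid()`).

They coincide to machine precision because `2V_i - Y_i = V_i + V_{i-1}`.
Fairness bands follow the convention in the health-resource equity
literature: `[0, 0.2)` absolute fairness, `[0.2, 0.3)` moderate,
`[0.3, 0.4)` relative, `[0.4, 0.6]` warning of inequality, `(0.6, 1)`
high inequality. Printed band edges in that literature overlap ("<0.2",
"0.2–0.3", ">0.4", ">0.6"); we chose left-closed/right-open intervals
(with `[0.4, 0.6]` closed on the right) as the unique total,
non-overlapping cover of `[0, 1)` — the only genuinely open choice, and
it affects none of the conventionally quoted values (0.09, 0.34, 0.61
fall strictly inside bands).

**Theil index.** The unweighted city-count form
`T = (1/n) Σ (Y_i/ȳ) ln(Y_i/ȳ)` is the default, with `0·ln 0 = 0` for
zero-count regions; a population-weighted variant is available behind the
`weights` argument of `theil_total()` but off by default, matching how
the index is usually reported for city counts. The decomposition over a
user-supplied grouping is the standard additive one,

* between: `T_B = Σ_p S_p ln(S_p / P_p)`,
* within: `T_w = Σ_p S_p T_p`,

with `S_p` group resource share, `P_p = n_p/n` group size share and `T_p`
the group-internal Theil index; `T = T_w + T_B` holds to 1e-12 and both
components are non-negative. The grouping is a required user input for a
meaningful decomposition: published analyses rarely state which grouping
(administrative strata, economic zones) produced their within/between
split, so none is assumed; with no grouping the whole panel forms one
group and the between component is zero.

## GM(1,1) grey forecasting

The original series `x0(k)` (strictly positive, `N ≥ 4`) is accumulated
into `x1(k) = Σ_{j≤k} x0(j)`. Least squares on the grey difference
equation `x0(k) + a·z1(k) = u`, with background value
`z1(k) = ½(x1(k) + x1(k-1))`, yields the development coefficient `a` and
grey action quantity `u`. The background coefficient ½ is the classic
construction and is exposed as the `lambda` argument.

Two numerical choices deserve note:

* **In-sample reconstruction uses the discrete solution of the
  difference equation itself**, not the continuous time-response
  exponential. The two differ at `O(a³)` per step; only the discrete form
  reproduces difference-equation-consistent data with exactly zero
  residuals, which is the calibration property the diagnostics rest on
  (a perfect generator round-trip must give `C = 0`, `P = 1`, grade 1).
  **Extrapolation** uses the time-response function
  `x̂1(k) = (x0(1) - u/a) e^{-a(k-1)} + u/a`, differenced back, as is
  standard.
* **Strict positivity** is required although the grey literature asks
  only for non-negative data: zeros break the accumulation/ratio
  structure. Monotonicity is *not* required (least squares is defined
  regardless) but a non-monotone input triggers a warning.

Accuracy is graded by the posterior difference ratio `C = S2/S1`
(residual s.d. over series s.d., population form by default — the
sample/population choice is unstated in common usage and exposed as an
option) and the small-error probability `P`, the fraction of residuals
strictly within `0.6745·S1` of their mean. Bands: level 1 `C < 0.35, P ≥
0.95`; level 2 `C < 0.50, P ≥ 0.80`; level 3 `C < 0.65, P ≥ 0.70`; level
4 otherwise. When C and P fall in different bands the *worse* grade
applies — the conservative resolution of a case the band table leaves
unstated. Extrapolation is licensed only at grades 1–2; a grade 3–4 model
still reports its forecast, flagged "unreliable", because planners
routinely want to see the gated number alongside the diagnostic that
disqualifies it. The residual-corrected re-extrapolation sometimes
mentioned alongside this gate is not implemented (it is never specified
concretely).

## ARIMA stage

Four deterministic steps on a univariate annual series:

1. **Differencing order**: the smallest `d ≤ 2` whose d-th difference
   passes a KPSS level-stationarity test at the 5% level (statistic vs
   the asymptotic critical value 0.463, Bartlett truncation
   `⌊4(n/100)^¼⌋`). KPSS-with-null-of-stationarity is the convention
   behind the usual `ndiffs` default; an ADF option (null = unit root,
   5% critical value −2.86) is provided. Both tests are implemented
   in-package because no pre-installed package supplies them. A constant
   series counts as stationary; failing at `max_d` is a warning, not an
   error.
2. **Order search**: exhaustive `(p, q)` grid (defaults ≤ 5) at the
   chosen `d`, each candidate fitted by maximum likelihood
   (`stats::arima`), smallest information criterion wins, ties broken by
   smaller `p + q` then smaller `p`. **BIC is the default criterion**,
   deliberately departing from the `auto.arima` AICc convention: on an
   exhaustive grid, AIC-type criteria select overparameterised ARMA
   models with non-vanishing probability even at n = 300 (spurious
   near-unit-circle AR/MA pairs buy several log-likelihood points; in our
   AR(1) φ = 0.6 experiments exhaustive AICc identified the true order in
   only ~a third of replicates, against 98% for BIC). BIC is
   order-consistent, which is what an identification-oriented grid search
   needs; AICc/AIC remain options for users who prioritise one-step
   predictive loss. The stepwise search `auto.arima` uses avoids part of
   the problem by never visiting most of the grid, but is itself a
   heuristic and reached only 84% here. For series longer than 150
   points (the same threshold `auto.arima` uses) the grid is pre-ranked
   by the conditional-sum-of-squares likelihood and only the top eight
   candidates are refitted by full maximum likelihood — a deterministic
   speed-up; the short annual series the package targets always use full
   ML on the whole grid.
3. **Constant policy**: a mean term for `d = 0`, a linear drift
   regressor for `d = 1`, no constant for `d = 2` — the standard policy
   for annual totals. An exactly-constant d-th difference (zero
   innovation variance) breaks the ML estimator, so that degenerate case
   short-circuits to the deterministic polynomial continuation with
   zero-width intervals.
4. **Forecast**: point forecasts with normal-theory 95% intervals
   (non-decreasing in horizon) and a Ljung–Box residual summary. Default
   horizon 5 years, mirroring the usual planning window.

Seasonal terms are out of scope: two decades of annual data cannot
support them.

## The synthetic world

`generate_panel()` emulates a provincial yearbook panel: 11 regions
observed 2003–2022 (both configurable), nurse counts growing
near-exponentially at a mean 7.8%/yr (the headline growth profile of the
kind of provincial panel this pipeline targets) with a between-region
growth s.d. of 0.01, baseline density 1 nurse per 1,000 population,
log-normal populations (median 3.5 M, sdlog 0.5) and areas (median
15,000 km², sdlog 0.4) — magnitudes typical of prefecture-level regions
of a mid-sized Chinese province — multiplicative log-normal noise
(s.d. 0.02), and between-region density dispersion `σ = 0.3` on the log
scale. Doctors, beds and technicians are derived from linearly
interpolated ratio trajectories (nurses per doctor 0.70 → 1.27, nurses
per bed 0.41 → 0.46, nurse share 0.28 → 0.45). Counts are rounded to
integers at the end, as yearbooks publish them; expected-value checks
therefore carry small tolerances, and the exact-zero-Gini check of the
equal-density configuration disables rounding. One global seed drives a
per-region substream, so adding a region never perturbs the others'
draws.

What the generator does *not* emulate: spatial correlation between
neighbouring regions, policy shocks (epidemic-driven reallocations),
urban/county stratum splits with their own dynamics, or any claim to
reproduce a real province's numbers. A green test on synthetic data
establishes that the estimators compute their definitions correctly and
that the pipeline's plumbing is sound — not that any real panel satisfies
the generator's assumptions.

Exact-oracle fixtures are independent of every estimator under test:
`make_two_point_fixture(w, s)` has closed-form Gini `w - s` from
trapezoid geometry, and `make_grey_consistent_series(a, u, x1_init, N)`
inverts the grey difference equation so the fitted `(a, u)` must round-trip
to machine precision.

## Degenerate inputs and numerical conventions

* Ratios with zero denominators are `NA`, never 0.
* Lorenz/Gini/Theil refuse all-zero resource vectors and non-positive
  basis weights; `x ln x → 0` handles zero counts inside Theil sums.
* GM(1,1) refuses `N < 4`, non-positive values, and `|a| < 1e-8`
  (constant series make `u/a` undefined).
* Theil decomposition identity is asserted at 1e-12; Gini route
  agreement at 1e-12; grey parameter round-trips at 1e-9.
* Equity stages are skipped (with an explanation in the bundle) for
  single-region panels; forecasting still runs on the total series.
* A grade-4 grey model is a warning, not a pipeline failure: the
  forecast table is produced with gate status "unqualified".

## Known limitations

* Gini and Theil are point estimates; no bootstrap intervals.
* The ARIMA stage is univariate — no covariates (economic indicators,
  policy variables), which is the main scientific limitation of
  demand forecasts of this kind.
* Grey modelling is limited to classic GM(1,1): no GM(1,N), rolling
  windows, or residual-corrected variants.
* The KPSS/ADF implementations use fixed asymptotic 5% critical values,
  adequate for the n ≥ 10 annual series the stage targets, not for
  general econometric use.
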