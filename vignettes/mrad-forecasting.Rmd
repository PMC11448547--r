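---
title: "Forecasting the maximum reported age at death: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting the maximum reported age at death: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mradforecast)
```

## The problem

The maximum reported age at death (MRAD) — currently 122 years — is the
standard statistic for quantifying the human lifespan. Whether and when that
record will be broken depends on two quantities: the survival law beyond age
110, and how many people will reach age 110 in the coming decades. This
package composes both into an unconditional probabilistic forecast of MRAD
for deaths in 2020–2100, restricted to the countries with rigorously
age-validated supercentenarian records.

## The exponential survival model beyond 110

Let $X$ be the age at death minus 110 of a person who reaches 110. The
mortality-plateau hypothesis — that the annual probability of death stops
increasing at extreme ages — corresponds to

$$X \sim \text{Exponential}(\lambda),$$

with density $f(x) = \lambda e^{-\lambda x}$ and mean excess lifetime
$1/\lambda$. By memorylessness the one-year survival probability
$s = e^{-\lambda}$ is the same at every age past 110; at rates near 0.7/yr
it is just under one half, which is why supercentenarian cohorts melt away
so quickly. The model has no covariates: it asserts that *conditional on
reaching 110*, sex, country, and region make no difference — an assumption
the package tests rather than assumes (see below).

For $N$ independent excess lifetimes, the maximum $X_{(N)}$ has

$$F_{(N)}(x) = \left(1 - e^{-\lambda x}\right)^N, \qquad
  f_{(N)}(x) = N \lambda e^{-\lambda x}\left(1 - e^{-\lambda x}\right)^{N-1},$$

implemented in `max_order_cdf()` / `max_order_pdf()` with the inverse-CDF
sampler `sample_max()` ($x = -\log(1 - u^{1/N})/\lambda$). Real-valued $N$
is accepted as the continuous extension, because the attainment cohorts
produced downstream are non-integer expected counts; rounding them would
introduce a small systematic bias for no benefit.

## Observation windows and truncation

Validated supercentenarian databases include a death only if it occurred
inside a country-specific calendar window $[b_c, e_c]$. Records are
therefore interval-truncated, and ignoring this can distort the rate
estimate substantially. Writing $t_i$ for the time person $i$ reached 110,
two cases arise:

* **C1** ($t_i \le b_c$): the person reached 110 before the window opened,
  so they are observable only if they died neither too early nor too late;
  the likelihood contribution is $f(x_i) / [F(e_c - t_i) - F(b_c - t_i)]$.
* **C2** ($t_i > b_c$): observable unless they outlived the window;
  contribution $f(x_i) / F(e_c - t_i)$.

The boundary $t = b$ is assigned to C1. An unbounded window end ($e =
\infty$) makes the C2 denominator 1 and the C1 denominator $1 - F(b - t)$.
`classify_case()` partitions any dataset; `log_contribution()` and
`loglik()` evaluate the truncated likelihood for both the exponential and
the generalized-Pareto (GP) family (location 0; shape $\xi = 0$ recovers the
exponential with $\lambda = 1/\sigma$).

A subtlety worth recording: truncation per se is not what biases the naive
estimator $n / \sum x_i$. If the attainment flow has been stationary for
much longer than $1/\lambda$ before the window opens, the deaths falling in
the window are unbiased exponential draws and the naive estimate is
consistent. The bias appears when observability genuinely restricts the
lifetimes that can be seen — short attainment histories and narrow windows —
and there it is large: the regression test uses a 3-year window with a
1-year attainment lead where the naive large-sample limit (computed by
quadrature over the attainment flow) is 1.13 against a true rate of 0.733,
while the truncation-aware MLE stays consistent.

## Estimation and model checks

`fit_mle()` maximizes the truncated likelihood. The exponential rate is the
root of the closed-form score equation, bracketed on $[10^{-6}, 50]$ per
year and solved to tolerance $10^{-12}$, so for untruncated data it
reproduces $n/\sum x_i$ essentially exactly. The GP fit optimizes
$(\log\sigma, \xi)$ from the exponential solution (Nelder–Mead, then a BFGS
polish). Stratified fits (`grouping = "sex"`, `"region"`,
`"sex-within-region"`, regions per `idl_regions()`) maximize independently
per group.

Uncertainty comes from a parametric bootstrap (`bootstrap_ci()`,
`confint()`): each record keeps its attainment time and window, and its
excess age is redrawn from the fitted law conditioned on observability
(inverse-CDF on the observable interval). The resampling design conditions
on $(t_i, b_c, e_c)$ because those are design quantities of the database,
not outcomes of the survival model; regenerating them would require a model
of the attainment process that the fit does not use. Refits that fail are
skipped; more than 5% failures aborts the interval.

Model assumptions are tested by nested likelihood-ratio tests with a BIC
complement (`lrt()`, `anova()`, `tail_model_tests()`): constant mortality
(exponential vs GP, $\chi^2_1$ with the shape unrestricted in sign),
region-specific, sex-specific, and sex-within-region rates. The BIC
difference is reported as $\Delta\text{BIC} = \mathrm{df}\,\ln n - \Lambda$
with $n$ the records entering both fits, so positive values favour the
simpler model.

## Posterior of the rate

With the scale-invariant vague prior $\pi(\lambda) \propto 1/\lambda$, the
truncated posterior kernel is

$$f(\lambda \mid X) \propto \lambda^{\,n-1} e^{-\lambda \sum x_i}
  \prod_{i \in C1}\left(e^{-\lambda(b_{c_i}-t_i)} - e^{-\lambda(e_{c_i}-t_i)}\right)^{-1}
  \prod_{i \in C2}\left(1 - e^{-\lambda(e_{c_i}-t_i)}\right)^{-1},$$

i.e. `loglik() - log(lambda)` up to a constant; for untruncated data it is
exactly Gamma$(n, \sum x_i)$, which the tests use as a conjugate oracle.
`sample_posterior()` runs a Gaussian random-walk Metropolis–Hastings chain
on $\log\lambda$ (with the Jacobian correction) — the log scale keeps
positivity without boundary rejections. Defaults: $1.1\times10^5$
iterations, $10^4$ burn-in, no thinning; when `proposal_sd` is not given it
is set to 2.4 times the curvature-based posterior standard deviation of
$\log\lambda$ at the MLE, which lands the acceptance rate in roughly
0.2–0.5 and gives effective sample sizes above 5000 on cohorts of around a
thousand records. Acceptance outside $[0.05, 0.95]$ and ESS below 100 emit
warnings; for $n < 10$ the propriety of the posterior is first asserted by
quadrature of the kernel over $[10^{-6}, 50]$.

## From population projections to attainment cohorts

Probabilistic population projections expose uncertainty as an ensemble of
equally weighted trajectories; here each trajectory reports the population
aged 110–114 at 5-year period ends (grid 2025–2080). Because roughly half
of those reaching 110 die within a year, the 110–114 stock badly
understates the flow of people who attained 110. Assuming attainments
spread uniformly over the preceding period $(t-5, t]$ and exponential
excess survival, the stock at $t$ relates to the period's attainment count
$N$ by the rectangle rule
$P = \tfrac{N}{5}\int_0^5 e^{-\lambda x}\,dx$, giving

$$N = M(\lambda)\,P, \qquad M(\lambda) = \frac{5\lambda}{1 - e^{-5\lambda}},$$

implemented in `cohort_multiplier()` ($M \to 1$ as $\lambda \to 0$, $M
\approx 5\lambda$ for large rates; $M(0.733) \approx 3.76$). The grid
year $t$ is read as covering attainments in $(t-5, t]$, so the 2025–2080
grid covers attainment years 2020–2080 — late enough attainers still have
two decades to die before 2100, and lifetimes are not right-truncated at
2100 since the forecast mass beyond age 130 is already small. Counts stay
real-valued throughout.

## Composing the unconditional MRAD distribution

The unconditional density of the century's maximum excess lifetime is the
mixture of the conditional maximum-order-statistic density over the two
posteriors — the rate posterior (from the death records) and the empirical
trajectory distribution (from the projections), which are independent
because they come from disjoint data. `forecast_mrad()` approximates it by
Monte Carlo with $T = 10^5$ iterations by default: draw $\lambda$ from the
posterior draws, draw a trajectory, set $N = M(\lambda)\sum_j P_j$, sample
the maximum by inverse CDF, record $110 + x$. Iterations with $N = 0$ are
tallied as the degenerate no-supercentenarian outcome and excluded from the
age draws — not resampled — so `exceedance_table()`, which divides by the
full $T$, stays unconditional. `density_summary()` evaluates a Gaussian
kernel density (Silverman bandwidth) on a 0.1-year grid padded by four
bandwidths, so its grid integral is 1 to within $10^{-3}$.

## The synthetic-data generator

Real validated supercentenarian records are registration-gated and the
projection trajectories derive from large external projection systems, so
the package ships a generator that emulates both input kinds with known
ground truth.

**Cohorts** (`simulate_dataset()`): each country contributes a homogeneous
Poisson stream of age-110 attainments at a configured intensity over
$[b - \text{lead}, e]$; excess lifetimes are exponential; a record is kept
only if the death lands in $[b, e]$; sexes are i.i.d. at the configured
female share. The stationary-intensity default keeps the inclusion
probability analytic (`inclusion_probability()`, used both to calibrate
intensities and as a test oracle). `default_cohort_config()` mimics the
gross shape of the real database: 13 countries with the most-represented
counts (US 504, FR 241, EW 157, JP 78, ES 60 of 1119), windows 10–35 years
wide, a 15-year lead, 92% female share, rate 0.733/yr. What it does *not*
emulate: growth of the attainment flow over calendar time, country-specific
window idiosyncrasies, sex- or region-dependent rates, or any record
verification noise — so passing tests certify the estimator under the
model's own sampling assumptions, not the data quality of a real registry.

**Trajectories** (`simulate_trajectories()`): trajectory $k$ has counts
$P_k(t_j) = \text{base}\cdot g^{j}\cdot\varepsilon_{kj}$ with log-normal
noise of total log-sd `dispersion`, correlated within a trajectory through
a shared factor (weight 0.7), so each trajectory is a coherent path rather
than independent scatter. Defaults — base 600 at 2025, growth 1.4 per
5-year period, dispersion 0.3 — were fixed once as a realistic scenario:
the 110–114 stock is a few hundred today, published projections show
order-of-magnitude growth by late century, and a dispersion of 0.3 makes
the 95% band roughly double the median by 2080. Log-normal noise guarantees
positivity and makes the median path exactly geometric (a test oracle).

## Numerical choices and degenerate inputs

* Decimal years everywhere; excess age from calendar dates as
  (death − birth in days)/365.2425 − 110, and $t$ = death time − $x$. The
  day-count convention for fractional ages is not standardized across
  registries; 365.2425 is the documented choice here.
* Year-only death dates (the US pattern) are imputed at July 1 by default,
  with January 1 / December 31 available for sensitivity runs
  (`impute_death_time()`); the reader maps the convention to a concrete
  calendar date, so its decimal death time differs from the idealized
  `year + 0.5` by at most 0.005 yr.
* Window-inclusion violations, missing windows, and negative excess ages
  are hard errors naming the offending record or country — the registry
  format guarantees inclusion, so a violation means corrupted input.
* The exponential score bracket $[10^{-6}, 50]$/yr spans mean excess
  lifetimes from 7 days to $10^6$ years; no plausible cohort leaves it.
* `sample_max()` uses `expm1`/`log1p` throughout, so it is accurate for
  cohort sizes far beyond $10^6$; the CDF inversion identity holds to
  $10^{-10}$ wherever the CDF is numerically inside $(0, 1)$.
* Empty denominators in `empirical_one_year_survival()` raise a classed
  condition (`mrad_undefined_value`) rather than returning a silent zero.

## Problem sizes used in the test suite

The suite exercises full-scale cohorts (about 1119 retained records) for
the parameter-recovery check (200 replicates) because the fit is a
root-find and costs milliseconds; Monte Carlo oracles use $10^4$–$10^5$
draws, and MH chains of 2–6 × 10^4 iterations, which resolve the conjugate
oracle comparisons well within their stated tolerances.

## Limitations

* The forecast applies only to deaths in the validated-registry countries
  and excludes currently living supercentenarians — omissions that make the
  exceedance probabilities conservative.
* The exponential plateau, and the absence of sex/region differences, are
  assumptions confirmed on present data; if mortality past 110 changes, the
  forecast does not apply.
* `empirical_one_year_survival()` is a raw proportion with no truncation
  adjustment — a diagnostic, not an estimator.
* The generator's stationary attainment process understates the real
  growth in attainment flows; a growing-intensity option would tighten the
  emulation at the cost of analytic oracles.

## A compact worked example

```{r pipeline, eval = FALSE}
d    <- simulate_dataset(default_cohort_config(seed = 1))
fit  <- fit_mle(d, "exponential")
confint(fit, B = 400, seed = 2)
tail_model_tests(d)

post <- sample_posterior(d, seed = 3)
ts   <- simulate_trajectories(trajectory_config(seed = 4))
fc   <- forecast_mrad(post, ts, T = 1e5, seed = 5)
exceedance_table(fc)
plot(fc)
```
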