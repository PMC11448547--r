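# mradforecast

Probabilistic forecasting of the maximum reported age at death (MRAD)
through 2100, for researchers in biodemography and extreme-value survival
analysis who work with validated supercentenarian death records and
probabilistic population projections.

## What it computes

People who reach age 110 appear to face a mortality plateau: the excess
lifetime `X = age at death − 110` is modelled as `X ~ Exponential(λ)`, so
the one-year survival probability `exp(−λ)` is the same at every age past
110. Validated registries record a death only if it falls inside a
country-specific calendar window `[b, e]`, which truncates the observable
lifetimes; the package fits λ by maximizing the window-truncated likelihood,
where a record whose subject reached 110 before the window opened (case C1)
contributes `f(x) / [F(e−t) − F(b−t)]` and one who reached 110 inside the
window (case C2) contributes `f(x) / F(e−t)`.

Forecasting the century's record combines three pieces:

1. **Posterior of λ** under the scale-invariant prior `π(λ) ∝ 1/λ` with the
   truncated likelihood, sampled by random-walk Metropolis–Hastings on
   `log λ` (`sample_posterior()`).
2. **Attainment cohorts** from probabilistic projection trajectories of the
   population aged 110–114: a period-end stock `P` converts to the number
   who attained 110 during the preceding five years via
   `N = M(λ)·P`, `M(λ) = 5λ / (1 − e^{−5λ})` (`cohort_multiplier()`).
3. **Order statistics of the maximum**: among `N` attainers the maximum
   excess lifetime has CDF `(1 − e^{−λx})^N`, sampled by inverse CDF
   (`sample_max()`).

`forecast_mrad()` mixes over both posteriors by Monte Carlo (default
`T = 1e5` iterations) and returns draws of the maximum age at death for
2020–2100, summarized by `exceedance_table()` and `density_summary()`.
Model assumptions (constant vs GP mortality, sex/region differences) are
checked with truncation-aware likelihood-ratio/BIC tests
(`tail_model_tests()`), and frequentist uncertainty comes from a parametric
bootstrap conditioned on each record's observability (`confint()`).

Because the real registry data are registration-gated, the package includes
a first-class synthetic-data module (`simulate_dataset()`,
`simulate_trajectories()`) that emulates window-truncated cohorts and
trajectory fans with known ground truth.

## Worked example

```r
library(mradforecast)

d   <- simulate_dataset(default_cohort_config(seed = 1))
d
#> Supercentenarian dataset: 1091 records, 13 countries
#> Truncation cases: C1 = 39, C2 = 1052

fit <- fit_mle(d, "exponential")
summary(fit)
#> exponential model, none grouping: n = 1091, logLik = -1376.179, BIC = 2759.35
#>   rate
#> 0.7128
#> Implied one-year survival beyond 110: 0.4902

confint(fit, B = 400, seed = 2)
#>          lower  estimate     upper
#> rate 0.6704805 0.7128468 0.7561631

post <- sample_posterior(d, n_iterations = 30000, burn_in = 5000, seed = 3)
post
#> Posterior sample of the exponential rate: 25000 draws
#> mean 0.7129, sd 0.0230; acceptance 0.44, ESS 5475

ts <- simulate_trajectories(trajectory_config(seed = 4))
fc <- forecast_mrad(post, ts, T = 1e5, seed = 5)
fc
#> MRAD forecast: 100000 Monte Carlo iterations (0 degenerate), seed 5
#> maximum age at death: median 128.3, 95% interval (125.6, 133.1)

exceedance_table(fc)
#>    age probability
#> 1  120     1.00000
#> 2  122     1.00000
#> 3  124     0.99989
#> 4  126     0.94742
#> 5  128     0.56569
#> 6  130     0.19492
#> ...
```

Reading: the generator produced 1091 window-truncated records at a true
rate of 0.733/yr; the truncation-aware MLE recovers 0.713 with bootstrap
95% CI (0.670, 0.756), implying a coin-flip one-year survival past 110. The
posterior matches (mean 0.713, sd 0.023). Composed with a growing
trajectory fan for the 110–114 population, the unconditional forecast says
the current 122-year record is essentially certain to be broken by 2100,
age 126 is reached with probability ≈ 0.95, and age 134 with probability
≈ 0.01 under this scenario.

Real data enter through the documented CSV dialects: `read_records()`
(records `id,country,sex,birth_date,death_date,death_year_only` plus a
windows table `country,window_start,window_end`) and `read_trajectories()`
(long format `trajectory_id,year,count` on the 5-year grid 2025–2080). A
thin command-line wrapper `exec/mrad` exposes
`describe`/`fit`/`test`/`posterior`/`forecast`/`simulate` subcommands over
the same functions.

See the methods vignette (`vignettes/mrad-forecasting.Rmd`) for the model's
assumptions, the truncation algebra, tuning defaults, and the design of the
synthetic generator.

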