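Package: mradforecast
Title: Probabilistic Forecasting of the Maximum Reported Age at Death
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Truncation-aware survival modelling of supercentenarian death
    records and probabilistic forecasting of the maximum reported age at
    death (MRAD) through 2100. Fits exponential and generalized-Pareto
    excess-lifetime models under country-specific observation windows by
    maximum likelihood with parametric-bootstrap intervals, samples the
    posterior of the exponential rate under the scale-invariant 1/lambda
    prior by Metropolis-Hastings, converts probabilistic projections of the
    110-114 population into age-110 attainment cohorts, and composes the
    pieces by Monte Carlo into an unconditional MRAD distribution with
    exceedance tables and density summaries. Includes a synthetic-data
    generator for window-truncated cohorts and projection trajectory sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
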