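test_that("truncated log-contributions match the closed forms", {
  r <- list(x = 1, t = 2000)
  expect_equal(log_contribution(r, list(b = 1990, e = Inf), exp_params(1)),
               -1.0)  # C2, unbounded end: plain log(lambda) - lambda*x
  expect_equal(log_contribution(r, list(b = 2000, e = Inf), exp_params(1)),
               -1.0)  # C1 with b - t = 0 and e = Inf: denominator 1
  val <- log_contribution(list(x = 0.8, t = 2000), list(b = 1990, e = 2002),
                          exp_params(0.7))
  expect_equal(val, log(0.7 * exp(-0.56)) - log(1 - exp(-1.4)),
               tolerance = 1e-12)
  # quadrature cross-check: the normalizing mass really is F(e - t)
  mass <- integrate(function(y) 0.7 * exp(-0.7 * y), 0, 2)$value
  expect_equal(val, log(0.7 * exp(-0.56)) - log(mass), tolerance = 1e-8)
  expect_error(log_contribution(list(x = 0.5, t = 1900),
                                list(b = 2000, e = 2001), exp_params(5)),
               "impossible")
})

test_that("dataset log-likelihood is additive and grid-consistent with the MLE", {
  empty <- mrad_data(data.frame(country = character(0), x = numeric(0),
                                t = numeric(0)),
                     data.frame(country = "US", b = 1980, e = 2010))
  expect_equal(loglik(empty, exp_params(0.7)), 0)

  one <- make_windowed(t = 1995, x = 2, b = 1990, e = 2005)
  two <- make_windowed(t = c(1995, 1995), x = c(2, 2), b = 1990, e = 2005)
  expect_equal(loglik(two, exp_params(0.9)), 2 * loglik(one, exp_params(0.9)))

  d <- fixture_small()$dataset
  grid <- seq(0.2, 3, length.out = 50)
  ll <- vapply(grid, function(l) loglik(d, exp_params(l)), numeric(1))
  lhat <- coef(fit_mle(d, "exponential"))
  expect_lt(abs(grid[which.max(ll)] - lhat), diff(grid[1:2]) + 1e-12)
})

test_that("untruncated exponential MLE equals the closed form n/sum(x)", {
  expect_equal(unname(coef(fit_mle(make_untruncated(2), "exponential"))), 0.5,
               tolerance = 1e-8)
  set.seed(11)
  x <- rexp(500, 1.3)
  fit <- fit_mle(make_untruncated(x), "exponential")
  expect_equal(unname(coef(fit)), length(x) / sum(x), tolerance = 1e-8)
})

test_that("GP fit is consistent and collapses to the exponential at xi = 0", {
  set.seed(21)
  xi <- 0.3; sigma <- 1.2
  x <- sigma / xi * ((1 - runif(5000))^(-xi) - 1)  # GP inverse CDF
  fit <- fit_mle(make_untruncated(x), "gp")
  expect_lt(abs(coef(fit)[["shape"]] - xi), 0.05)

  d <- fixture_small()$dataset
  lam <- 0.9
  expect_equal(loglik(d, gp_params(1 / lam, 1e-6)),
               loglik(d, exp_params(lam)), tolerance = 1e-4)
})

test_that("stratified fits maximize per group and sum the log-likelihood", {
  d <- simulate_dataset(default_cohort_config(n_target = 400, seed = 3))
  f0 <- fit_mle(d, "exponential", "none")
  fs <- fit_mle(d, "exponential", "sex")
  expect_gte(fs$logLik, f0$logLik - 1e-8)
  expect_equal(fs$df, length(unique(d$records$sex)))
  # group estimates equal the fits on the group subsets
  for (s in unique(d$records$sex)) {
    sub <- mrad_data(d$records[d$records$sex == s, ], d$windows)
    expect_equal(fs$groups[[s]]$rate,
                 fit_mle(sub, "exponential")$groups[[1]]$rate,
                 tolerance = 1e-9)
  }
})

test_that("likelihood-ratio and BIC arithmetic follow the nested-test convention", {
  expect_equal(delta_bic(0.39, 1, 1119), 6.63, tolerance = 5e-3)
  expect_equal(delta_bic(6.74, 3, 1119), 14.32, tolerance = 5e-3)
  expect_equal(delta_bic(0.42, 1, 1119), 6.60, tolerance = 5e-3)
  expect_equal(delta_bic(0, 1, round(exp(1))), log(round(exp(1))))

  d <- simulate_dataset(default_cohort_config(n_target = 400, seed = 3))
  t1 <- lrt(fit_mle(d, "exponential"), fit_mle(d, "gp"))
  expect_gte(t1$statistic, 0)
  expect_equal(t1$p.value,
               pchisq(t1$statistic, t1$df, lower.tail = FALSE))
  expect_equal(t1$delta_bic, t1$df * log(d$n) - t1$statistic)
  # anova() is the classic surface for the same comparison
  t2 <- anova(fit_mle(d, "exponential"), fit_mle(d, "exponential", "region"))
  expect_s3_class(t2, "mrad_lrt")
  # a fit pair where the "alternative" has lower likelihood is an error
  bad <- fit_mle(d, "exponential")
  bad$df <- 2L; bad$logLik <- bad$logLik - 1
  expect_error(lrt(fit_mle(d, "exponential"), bad), "optimizer")
})

test_that("model-assumption battery has the published table's shape", {
  d <- simulate_dataset(default_cohort_config(n_target = 600, seed = 9))
  tab <- tail_model_tests(d)
  expect_true(all(c("Constant mortality (exponential vs. GP)",
                    "Region-specific mortality",
                    "Sex-specific mortality") %in% tab$test))
  expect_true(all(tab$statistic >= 0))
  expect_true(all(tab$p.value >= 0 & tab$p.value <= 1))
  expect_equal(tab$delta_bic, tab$df * log(tab$n) - tab$statistic)
})

test_that("implied one-year survival is exp(-rate)", {
  expect_equal(one_year_survival(exp_params(log(2))), 0.5)
  expect_equal(one_year_survival(exp_params(1e-9)), 1, tolerance = 1e-8)
  expect_equal(round(one_year_survival(exp_params(0.733)), 4), 0.4805)
})

test_that("maximum-order-statistic density, CDF, and sampler are coherent", {
  x <- c(0.5, 1, 3, 7)
  expect_equal(max_order_pdf(x, 0.8, 1), 0.8 * exp(-0.8 * x))
  expect_error(max_order_pdf(-1, 0.8, 1), "nonnegative")

  # density integrates to one at the published magnitudes
  lam <- 1 / 1.34; N <- 2974
  total <- integrate(function(y) max_order_pdf(y, lam, N), 0, Inf,
                     subdivisions = 1000L)$value
  expect_equal(total, 1, tolerance = 1e-6)

  # pdf is the derivative of the cdf
  h <- 1e-5
  fd <- (max_order_cdf(10 + h, 0.7, 1000) - max_order_cdf(10 - h, 0.7, 1000)) /
    (2 * h)
  expect_equal(max_order_pdf(10, 0.7, 1000), fd, tolerance = 1e-6)

  expect_equal(max_order_cdf(0, 0.7, 1000), 0)
  expect_equal(max_order_cdf(1e6, 0.7, 1000), 1)
  expect_equal(1 - max_order_cdf(10, 0.7, 1000), 1 - (1 - exp(-7))^1000,
               tolerance = 1e-12)
  # monotone in x, non-increasing in N at fixed x > 0
  xs <- seq(0.1, 20, by = 0.5)
  expect_true(all(diff(max_order_cdf(xs, 0.7, 50)) >= 0))
  Ns <- c(1, 10, 100, 1000, 1e4)
  expect_true(all(diff(vapply(Ns, function(N) max_order_cdf(5, 0.7, N),
                              numeric(1))) <= 0))

  # inverse-CDF sampler inverts the CDF and passes a KS test
  x0 <- c(6, 9.7, 13)  # CDF numerically inside (0, 1) at N = 500
  expect_equal(sample_max(0.733, 500, max_order_cdf(x0, 0.733, 500)), x0,
               tolerance = 1e-10)
  expect_error(sample_max(0.733, 500, 1.2), "\\(0, 1\\)")
  set.seed(8)
  draws <- sample_max(0.733, 500, runif(1e4))
  ks <- suppressWarnings(ks.test(draws, function(q) max_order_cdf(q, 0.733, 500)))
  expect_gt(ks$p.value, 0.01)
})

test_that("conditional observable density integrates to one for both families and cases", {
  for (params in list(exp_params(0.733), gp_params(1.4, 0.15),
                      gp_params(1.3, -0.08))) {
    for (case in c("C1", "C2")) {
      t <- if (case == "C1") 1995 else 2003
      b <- 2000; e <- 2012
      lo <- max(b - t, 0); hi <- e - t
      r <- function(y) exp(vapply(y, function(yy) {
        log_contribution(list(x = yy, t = t), list(b = b, e = e), params)
      }, numeric(1)))
      mass <- integrate(r, lo, hi, subdivisions = 500L, rel.tol = 1e-9)$value
      expect_equal(mass, 1, tolerance = 1e-6)
    }
  }
})

test_that("parametric bootstrap is reproducible and matches the Wald interval untruncated", {
  set.seed(3)
  x <- rexp(1119, 0.733)
  d <- make_untruncated(x)
  fit <- fit_mle(d, "exponential")
  ci1 <- bootstrap_ci(fit = fit, B = 400, seed = 17)
  ci2 <- bootstrap_ci(fit = fit, B = 400, seed = 17)
  expect_identical(ci1, ci2)

  lhat <- unname(coef(fit))
  wald <- lhat * (1 + c(-1, 1) * 1.96 / sqrt(d$n))
  expect_lt(abs(ci1[1, "lower"] - wald[1]), 0.1 * abs(wald[1]))
  expect_lt(abs(ci1[1, "upper"] - wald[2]), 0.1 * abs(wald[2]))
  expect_lt(ci1[1, "lower"], lhat)
  expect_gt(ci1[1, "upper"], lhat)

  # confint() is the classic surface over the same computation
  ci3 <- confint(fit, level = 0.95, B = 100, seed = 17)
  expect_equal(dim(ci3), c(1L, 3L))
})
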