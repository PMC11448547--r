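# Posterior inference on the exponential rate under the scale-invariant
# 1/lambda prior, with the window-truncated likelihood, via random-walk
# Metropolis-Hastings on log(lambda).

# sufficient statistics of the truncated exponential posterior kernel
posterior_stats <- function(data) {
  stopifnot(inherits(data, "mrad_data"))
  bb <- obs_bounds(data)
  list(n = data$n, sumx = sum(data$records$x), lo = bb$lo, hi = bb$hi)
}

log_posterior_stats <- function(lambda, st) {
  if (lambda <= 0) return(-Inf)
  elo <- exp(-lambda * st$lo)
  ehi <- ifelse(is.finite(st$hi), exp(-lambda * st$hi), 0)
  (st$n - 1) * log(lambda) - lambda * st$sumx - sum(log(elo - ehi))
}

#' Unnormalized log-posterior of the exponential rate
#'
#' With the vague scale-invariant prior proportional to `1/lambda` and the
#' window-truncated exponential likelihood, the log kernel is
#' `(n - 1) * log(lambda) - lambda * sum(x) - sum(log(D_i))` where `D_i` is
#' record i's truncation denominator (`exp(-lambda*(b - t)) -
#' exp(-lambda*(e - t))` for C1, `1 - exp(-lambda*(e - t))` for C2). It
#' equals `loglik(data, exp_params(lambda)) - log(lambda)` up to an additive
#' constant.
#'
#' @param lambda rate value(s); nonpositive values give `-Inf`.
#' @param data an [mrad_data] object with at least one record.
#' @return Unnormalized log-posterior value(s).
#' @export
log_posterior <- function(lambda, data) {
  st <- posterior_stats(data)
  if (st$n < 1) stop("at least one record is required")
  vapply(lambda, log_posterior_stats, numeric(1), st = st)
}

# initial-positive-sequence effective sample size from the empirical acf
ess_draws <- function(draws) {
  m <- length(draws)
  if (m < 10 || stats::sd(draws) == 0) return(m)
  rho <- stats::acf(draws, lag.max = min(1000L, m %/% 2), plot = FALSE,
                    demean = TRUE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
  m / (1 + 2 * sum(rho))
}

#' Sample the posterior of the exponential rate by Metropolis-Hastings
#'
#' Gaussian random-walk proposal on `log(lambda)` (with the Jacobian
#' correction), which keeps positivity without boundary rejections. When
#' `proposal_sd` is `NULL` the scale is set to 2.4 times the curvature-based
#' posterior standard deviation of `log(lambda)` at the MLE, which lands the
#' acceptance rate in roughly 0.2-0.5. Warnings are emitted for acceptance
#' outside `[0.05, 0.95]` or an effective sample size below 100. For very
#' small datasets (n < 10) propriety of the posterior is asserted by
#' quadrature of the kernel over `[1e-6, 50]` before sampling.
#'
#' @param data an [mrad_data] object.
#' @param n_iterations total MH iterations (default 1.1e5).
#' @param proposal_sd random-walk standard deviation on the log scale, or
#'   `NULL` for automatic tuning.
#' @param burn_in iterations discarded from the front (default 1e4).
#' @param thinning keep every `thinning`-th post-burn-in draw.
#' @param seed integer seed; chains are bit-reproducible given the seed.
#' @return Object of class `mrad_posterior`: list with `draws`,
#'   `n_iterations`, `burn_in`, `thinning`, `acceptance_rate`, `seed`,
#'   `effective_sample_size`.
#' @export
sample_posterior <- function(data, n_iterations = 110000, proposal_sd = NULL,
                             burn_in = 10000, thinning = 1, seed = NULL) {
  stopifnot(inherits(data, "mrad_data"), n_iterations > burn_in,
            burn_in >= 0, thinning >= 1)
  st <- posterior_stats(data)
  if (st$n < 1) stop("at least one record is required")
  lp <- function(l) log_posterior_stats(l, st)

  if (st$n < 10) {
    grid <- exp(seq(log(1e-6), log(50), length.out = 200))
    m <- max(vapply(grid, lp, numeric(1)))
    z <- stats::integrate(function(l) {
      vapply(l, function(li) exp(lp(li) - m), numeric(1))
    }, 1e-6, 50, subdivisions = 500L)$value
    if (!is.finite(z) || z <= 0)
      stop("posterior is not integrable on [1e-6, 50] for this dataset")
  }

  start <- fit_exp_group(data$records$x, st$lo, st$hi)$rate
  if (is.null(proposal_sd)) {
    g <- function(eta) lp(exp(eta))
    eta0 <- log(start); d <- 1e-4
    h <- (g(eta0 + d) - 2 * g(eta0) + g(eta0 - d)) / d^2
    proposal_sd <- if (is.finite(h) && h < 0) 2.4 / sqrt(-h) else 0.1
  }
  stopifnot(proposal_sd > 0)

  if (!is.null(seed)) set.seed(seed)
  chain <- numeric(n_iterations)
  eta <- log(start)
  cur <- lp(exp(eta)) + eta  # log target in eta includes the Jacobian
  steps <- stats::rnorm(n_iterations, 0, proposal_sd)
  logu <- log(stats::runif(n_iterations))
  acc <- 0L
  for (i in seq_len(n_iterations)) {
    eta_p <- eta + steps[i]
    prop <- lp(exp(eta_p)) + eta_p
    if (logu[i] < prop - cur) {
      eta <- eta_p; cur <- prop; acc <- acc + 1L
    }
    chain[i] <- eta
  }
  draws <- exp(chain[seq(burn_in + 1L, n_iterations, by = thinning)])
  rate <- acc / n_iterations
  ess <- ess_draws(draws)
  if (rate < 0.05 || rate > 0.95)
    warning(sprintf("MH acceptance rate %.3f outside [0.05, 0.95]; retune proposal_sd",
                    rate))
  if (ess < 100)
    warning(sprintf("effective sample size %.0f below 100", ess))
  structure(list(draws = draws, n_iterations = n_iterations,
                 burn_in = burn_in, thinning = thinning,
                 acceptance_rate = rate, seed = seed,
                 effective_sample_size = ess, proposal_sd = proposal_sd),
            class = "mrad_posterior")
}

#' Normal approximation (mean and variance) of a posterior sample
#'
#' The sample mean and variance of the draws, used for the overlay comparison
#' of the MCMC posterior with its large-sample normal approximation.
#'
#' @param sample an `mrad_posterior` (effective sample size should be at
#'   least 100) or numeric vector of draws.
#' @return Named numeric vector `c(mean, variance)`.
#' @export
normal_approximation <- function(sample) {
  draws <- if (inherits(sample, "mrad_posterior")) sample$draws else sample
  if (inherits(sample, "mrad_posterior") &&
      sample$effective_sample_size < 100)
    warning("effective sample size below 100; moments are unreliable")
  m <- mean(draws)
  c(mean = m, variance = mean((draws - m)^2) * length(draws) /
      max(length(draws) - 1, 1))
}

#' @export
print.mrad_posterior <- function(x, ...) {
  na <- normal_approximation(x)
  cat(sprintf(paste0("Posterior sample of the exponential rate: %d draws\n",
                     "mean %.4f, sd %.4f; acceptance %.2f, ESS %.0f\n"),
              length(x$draws), na["mean"], sqrt(na["variance"]),
              x$acceptance_rate, x$effective_sample_size))
  invisible(x)
}

#' @export
summary.mrad_posterior <- function(object, ...) {
  q <- stats::quantile(object$draws, c(0.025, 0.25, 0.5, 0.75, 0.975))
  na <- normal_approximation(object)
  out <- list(mean = unname(na["mean"]), variance = unname(na["variance"]),
              quantiles = q, acceptance_rate = object$acceptance_rate,
              ess = object$effective_sample_size,
              n_draws = length(object$draws))
  class(out) <- "summary.mrad_posterior"
  out
}

#' @export
print.summary.mrad_posterior <- function(x, ...) {
  cat(sprintf("%d draws; mean %.4f, variance %.3g, acceptance %.2f, ESS %.0f\n",
              x$n_draws, x$mean, x$variance, x$acceptance_rate, x$ess))
  print(round(x$quantiles, 4))
  invisible(x)
}

#' Kernel density of the rate posterior with normal overlay
#'
#' Gaussian kernel with Silverman's bandwidth; the dashed overlay is the
#' normal approximation matched to the sample moments.
#'
#' @param x an `mrad_posterior`.
#' @param overlay_normal draw the matched-normal curve.
#' @param ... passed to `plot()`.
#' @export
plot.mrad_posterior <- function(x, overlay_normal = TRUE, ...) {
  d <- stats::density(x$draws, bw = "nrd0")
  graphics::plot(d, xlab = expression(lambda), main = "Posterior of the rate",
                 ...)
  if (overlay_normal) {
    na <- normal_approximation(x)
    graphics::curve(stats::dnorm(l, na["mean"], sqrt(na["variance"])),
                    xname = "l", add = TRUE, lty = 2, col = 2)
  }
  invisible(x)
}
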