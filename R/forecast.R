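# Monte Carlo composition of rate-posterior draws and projection
# trajectories into the unconditional MRAD distribution.

#' Monte Carlo forecast of the maximum reported age at death
#'
#' Each iteration draws a rate uniformly with replacement from the posterior
#' draws, draws a trajectory uniformly with replacement from the trajectory
#' set, converts the trajectory to the century total of age-110 attainers
#' `N = total_attainments(trajectory, lambda)`, and samples the maximum
#' excess lifetime among `N` exponential lifetimes by inverse CDF
#' ([sample_max()]), recording `110 + x`. Rate and trajectory are drawn
#' independently, reflecting posteriors built from disjoint data sources.
#' Iterations with `N = 0` record the degenerate no-supercentenarian outcome:
#' they are tallied (`n_degenerate`) and excluded from `ages`, so exceedance
#' probabilities computed over all `T` iterations remain unconditional. All
#' `T` iterations degenerate is an error.
#'
#' @param posterior an `mrad_posterior` or a numeric vector of positive rate
#'   draws (a length-1 vector gives the fixed-rate conditional forecast).
#' @param trajectories a [trajectory_set()].
#' @param T number of Monte Carlo iterations (default 1e5).
#' @param seed integer seed; forecasts are reproducible given the seed.
#' @return Object of class `mrad_samples`: list with `ages` (maximum ages at
#'   death, each >= 110), `T`, `n_degenerate`, `seed`, `provenance`.
#' @export
forecast_mrad <- function(posterior, trajectories, T = 1e5, seed = NULL) {
  draws <- if (inherits(posterior, "mrad_posterior")) posterior$draws
           else as.numeric(posterior)
  stopifnot(length(draws) >= 1, all(draws > 0),
            inherits(trajectories, "trajectory_set"), T >= 1)
  totals <- rowSums(trajectories$counts)
  if (!is.null(seed)) set.seed(seed)
  lam <- draws[sample.int(length(draws), T, replace = TRUE)]
  S <- totals[sample.int(length(totals), T, replace = TRUE)]
  N <- cohort_multiplier(lam) * S
  u <- stats::runif(T)
  deg <- N <= 0
  if (all(deg))
    stop("all ", T, " iterations produced zero attainers: empty trajectory set")
  x <- rep(NA_real_, T)
  x[!deg] <- -log(-expm1(log(u[!deg]) / N[!deg])) / lam[!deg]
  structure(list(ages = 110 + x[!deg], T = as.integer(T),
                 n_degenerate = sum(deg), seed = seed,
                 provenance = list(
                   posterior = if (inherits(posterior, "mrad_posterior"))
                     "mrad_posterior" else "fixed draws",
                   trajectories = trajectories$source)),
            class = "mrad_samples")
}

#' Exceedance probabilities of the forecast MRAD
#'
#' For each age `a`, the fraction of Monte Carlo iterations whose maximum age
#' at death reaches `a` (a person attains age `a` at last birthday iff MRAD
#' >= `a`). Degenerate iterations count as MRAD below 110, so the denominator
#' is the full iteration count `T`.
#'
#' @param samples an `mrad_samples` object with at least one retained draw.
#' @param ages integer age grid (default 120 to 142 by 2).
#' @return Data frame of class `exceedance_table` with columns `age` and
#'   `probability`, non-increasing in age.
#' @export
#' @examples
#' \donttest{
#' ts <- simulate_trajectories(trajectory_config(seed = 1))
#' fc <- forecast_mrad(0.733, ts, T = 1e4, seed = 1)
#' exceedance_table(fc)
#' }
exceedance_table <- function(samples, ages = seq(120, 142, by = 2)) {
  stopifnot(inherits(samples, "mrad_samples"), length(samples$ages) >= 1)
  prob <- vapply(ages, function(a) sum(samples$ages >= a), numeric(1)) /
    samples$T
  structure(data.frame(age = ages, probability = prob),
            class = c("exceedance_table", "data.frame"))
}

#' Kernel density summary of the forecast MRAD
#'
#' Gaussian-kernel density with Silverman's bandwidth by default, evaluated
#' on a 0.1-year grid spanning the draws (padded by 4 bandwidths so the grid
#' integral is 1 to within 1e-3).
#'
#' @param samples an `mrad_samples` object with at least 100 retained draws.
#' @param bandwidth kernel bandwidth in years, or `NULL` for Silverman.
#' @return Data frame with columns `age` and `density`; attribute
#'   `bandwidth`.
#' @export
density_summary <- function(samples, bandwidth = NULL) {
  stopifnot(inherits(samples, "mrad_samples"), length(samples$ages) >= 100)
  d <- samples$ages
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(d) else bandwidth
  stopifnot(bw > 0)
  grid <- seq(min(d) - 4 * bw, max(d) + 4 * bw, by = 0.1)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, mean = d, sd = bw)),
                 numeric(1))
  structure(data.frame(age = grid, density = dens), bandwidth = bw)
}

#' @export
print.mrad_samples <- function(x, ...) {
  cat(sprintf(paste0("MRAD forecast: %d Monte Carlo iterations ",
                     "(%d degenerate), seed %s\n"),
              x$T, x$n_degenerate,
              if (is.null(x$seed)) "unset" else x$seed))
  if (length(x$ages))
    cat(sprintf("maximum age at death: median %.1f, 95%% interval (%.1f, %.1f)\n",
                stats::median(x$ages),
                stats::quantile(x$ages, 0.025),
                stats::quantile(x$ages, 0.975)))
  invisible(x)
}

#' @export
summary.mrad_samples <- function(object, ...) {
  out <- list(T = object$T, n_degenerate = object$n_degenerate,
              quantiles = stats::quantile(object$ages,
                                          c(0.025, 0.25, 0.5, 0.75, 0.975)),
              mean = mean(object$ages),
              exceedance = exceedance_table(object))
  class(out) <- "summary.mrad_samples"
  out
}

#' @export
print.summary.mrad_samples <- function(x, ...) {
  cat(sprintf("T = %d iterations, %d degenerate\n", x$T, x$n_degenerate))
  cat(sprintf("mean MRAD %.2f; quantiles:\n", x$mean))
  print(round(x$quantiles, 2))
  cat("\nExceedance probabilities:\n")
  print(x$exceedance, row.names = FALSE)
  invisible(x)
}

#' @export
quantile.mrad_samples <- function(x, probs = c(0.025, 0.5, 0.975), ...) {
  stats::quantile(x$ages, probs = probs, ...)
}

#' Histogram of forecast MRAD draws with kernel density overlay
#'
#' @param x an `mrad_samples` object.
#' @param ... passed to `hist()`.
#' @export
plot.mrad_samples <- function(x, ...) {
  graphics::hist(x$ages, breaks = 50, freq = FALSE,
                 xlab = "maximum reported age at death",
                 main = "Unconditional MRAD forecast", ...)
  ds <- density_summary(x)
  graphics::lines(ds$age, ds$density, col = 2, lwd = 2)
  invisible(x)
}
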