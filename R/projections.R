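# Probabilistic projection trajectories of the 110-114 population and their
# conversion to age-110 attainment cohorts.

#' Attainment-cohort multiplier
#'
#' Converts a point-in-time count of the 110-114 age band into the number of
#' people who attained age 110 during the preceding 5 years, assuming
#' exponential excess survival at rate `lambda` and uniform attainment over
#' the period: `M = 5 * lambda / (1 - exp(-5 * lambda))`. `M` decreases to 1
#' as `lambda` approaches 0 and grows like `5 * lambda` for large rates.
#'
#' @param lambda exponential rate(s), > 0.
#' @return Multiplier(s) `M > 1`.
#' @export
#' @examples
#' cohort_multiplier(0.733)
cohort_multiplier <- function(lambda) {
  if (any(lambda <= 0)) stop("'lambda' must be positive")
  5 * lambda / (-expm1(-5 * lambda))
}

#' Construct a set of projection trajectories
#'
#' @param counts numeric matrix, one row per trajectory and one column per
#'   grid year, all counts nonnegative; a single trajectory may be given as a
#'   vector.
#' @param years period-end calendar years forming a contiguous 5-year grid
#'   (e.g. `seq(2025, 2080, 5)`); year `t` holds the 110-114 count at `t`,
#'   fed by attainments over `(t - 5, t]`.
#' @param source label recording where the trajectories came from.
#' @return Object of class `trajectory_set` with elements `years`, `counts`,
#'   `source`.
#' @export
trajectory_set <- function(counts, years, source = "unspecified") {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  years <- as.numeric(years)
  stopifnot(ncol(counts) == length(years), nrow(counts) >= 1)
  if (length(years) > 1 && any(diff(years) != 5))
    stop("'years' must form a contiguous 5-year grid")
  if (any(counts < 0) || anyNA(counts)) stop("all counts must be nonnegative")
  colnames(counts) <- years
  if (is.null(rownames(counts))) rownames(counts) <- seq_len(nrow(counts))
  structure(list(years = years, counts = counts, source = source),
            class = "trajectory_set")
}

#' Per-period and total age-110 attainment counts for a trajectory
#'
#' Applies the [cohort_multiplier()] to each period-end count: the grid year
#' `t` contributes `M(lambda) * P_t` people attaining age 110 during
#' `(t - 5, t]`. Counts are kept real-valued throughout.
#'
#' @param trajectory a named numeric vector of counts by grid year, or a
#'   single-row `trajectory_set`.
#' @param lambda exponential rate > 0.
#' @return `attainments()`: named vector of per-period attainment counts;
#'   `total_attainments()`: their sum (for a `trajectory_set`, a vector of
#'   totals, one per trajectory).
#' @export
attainments <- function(trajectory, lambda) {
  if (inherits(trajectory, "trajectory_set")) {
    stopifnot(nrow(trajectory$counts) == 1)
    trajectory <- trajectory$counts[1, ]
  }
  cohort_multiplier(lambda) * trajectory
}

#' @rdname attainments
#' @export
total_attainments <- function(trajectory, lambda) {
  if (inherits(trajectory, "trajectory_set"))
    return(cohort_multiplier(lambda) * rowSums(trajectory$counts))
  sum(attainments(trajectory, lambda))
}

#' Read projection trajectories from long-format CSV
#'
#' Dialect: columns `trajectory_id,year,count`, one row per (trajectory, grid
#' year), header required. Every trajectory must cover the identical
#' contiguous 5-year grid; ragged grids or negative counts are errors naming
#' the offending trajectory.
#'
#' @param source file path, connection, or literal CSV text.
#' @return A [trajectory_set()].
#' @export
read_trajectories <- function(source) {
  df <- read_csv_source(source)
  need <- c("trajectory_id", "year", "count")
  if (!all(need %in% names(df)))
    stop("trajectories CSV must have columns: ", paste(need, collapse = ", "))
  df$year <- as.numeric(df$year)
  df$count <- as.numeric(df$count)
  years <- sort(unique(df$year))
  ids <- unique(df$trajectory_id)
  counts <- matrix(NA_real_, nrow = length(ids), ncol = length(years),
                   dimnames = list(ids, years))
  for (id in ids) {
    sub <- df[df$trajectory_id == id, ]
    if (nrow(sub) != length(years) || anyDuplicated(sub$year) ||
        !setequal(sub$year, years))
      stop("trajectory '", id, "' does not cover the full year grid")
    if (any(sub$count < 0) || anyNA(sub$count))
      stop("trajectory '", id, "' has negative or missing counts")
    counts[id, as.character(sub$year)] <- sub$count
  }
  trajectory_set(counts, years, source = "csv")
}

#' Write a trajectory set in the long-format CSV dialect
#'
#' @param ts a `trajectory_set`.
#' @param path output file path.
#' @return Invisibly, `ts`.
#' @export
write_trajectories <- function(ts, path) {
  stopifnot(inherits(ts, "trajectory_set"))
  df <- data.frame(
    trajectory_id = rep(rownames(ts$counts), each = length(ts$years)),
    year = rep(ts$years, times = nrow(ts$counts)),
    count = as.vector(t(ts$counts)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(ts)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d trajectories on grid %s-%s (step 5), source: %s\n",
              nrow(x$counts), min(x$years), max(x$years), x$source))
  q <- apply(x$counts, 2, stats::quantile, c(0.025, 0.5, 0.975))
  print(round(q, 1))
  invisible(x)
}

#' Fan chart of a trajectory set
#'
#' Median and central 95% band of the 110-114 counts across trajectories.
#'
#' @param x a `trajectory_set`.
#' @param ... passed to `plot()`.
#' @export
plot.trajectory_set <- function(x, ...) {
  q <- apply(x$counts, 2, stats::quantile, c(0.025, 0.5, 0.975))
  graphics::plot(x$years, q[2, ], type = "b", ylim = range(q), pch = 16,
                 xlab = "year", ylab = "population aged 110-114", ...)
  graphics::lines(x$years, q[1, ], lty = 2)
  graphics::lines(x$years, q[3, ], lty = 2)
  invisible(x)
}
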