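#' Interval urinary excretion series
#'
#' The observable fitted throughout the package: urine collected between
#' consecutive sample times, expressed per species as an average rate
#' (umol/hr) over each interval (right-endpoint convention).
#'
#' @param sample_times strictly increasing collection times (hr), length
#'   `n + 1` for `n` intervals.
#' @param rate_iAs,rate_MMA,rate_DMA per-interval rates (umol/hr), each of
#'   length `n`, non-negative.
#' @return an `excretion_series` object.
#' @export
excretion_series <- function(sample_times, rate_iAs, rate_MMA, rate_DMA) {
  n <- length(sample_times) - 1
  if (n < 1) stop("need at least two sample times")
  if (any(diff(sample_times) <= 0)) {
    stop("sample_times must be strictly increasing")
  }
  rates <- data.frame(rate_iAs = rate_iAs, rate_MMA = rate_MMA,
                      rate_DMA = rate_DMA)
  if (nrow(rates) != n) stop("rates must have length(sample_times) - 1 rows")
  if (any(as.matrix(rates) < 0)) stop("excretion rates must be non-negative")
  structure(list(sample_times = sample_times, rates = rates),
            class = "excretion_series")
}

#' Interval excretion rates from cumulative urine amounts
#'
#' Mirrors the measurement protocol: the amount of each arsenical
#' accumulated in the urine since the previous collection, divided by the
#' interval length, giving a rate over `(t_i, t_{i+1}]`.
#'
#' @param cumulative_urine data frame (or matrix) with columns `UiAs`,
#'   `UMMAs`, `UDMAs` (cumulative umol) evaluated at `sample_times`; an
#'   `as_trajectory` whose time grid contains all sample times is also
#'   accepted.
#' @param sample_times strictly increasing collection times (hr).
#' @return an [excretion_series()].
#' @export
interval_excretion_rates <- function(cumulative_urine, sample_times) {
  if (any(duplicated(sample_times))) stop("duplicate sample times")
  if (any(diff(sample_times) <= 0)) {
    stop("sample_times must be strictly increasing")
  }
  if (inherits(cumulative_urine, "as_trajectory")) {
    idx <- match(sample_times, cumulative_urine$time)
    if (any(is.na(idx))) {
      stop("trajectory time grid does not contain all sample times")
    }
    cumulative_urine <- cumulative_urine[idx, c("UiAs", "UMMAs", "UDMAs")]
  }
  u <- as.matrix(as.data.frame(cumulative_urine)[, c("UiAs", "UMMAs", "UDMAs")])
  if (nrow(u) != length(sample_times)) {
    stop("cumulative series must be defined at every sample time")
  }
  du <- apply(u, 2, diff)
  du <- matrix(du, ncol = 3)
  if (any(du < -1e-9)) stop("cumulative urine series must be non-decreasing")
  du[du < 0] <- 0
  dt <- diff(sample_times)
  excretion_series(sample_times, du[, 1] / dt, du[, 2] / dt, du[, 3] / dt)
}

#' Species composition percentages
#'
#' Shares of the three arsenicals in a triple of amounts, concentrations
#' or rates, as percentages summing to 100. Published composition tables
#' print integers; use [round_half_up()] for that comparison.
#'
#' @param iAs,MMA,DMA non-negative amounts (any common unit); sum `> 0`.
#' @return named vector `c(iAs=, MMA=, DMA=)` of percentages (unrounded).
#' @export
species_percentages <- function(iAs, MMA, DMA) {
  v <- c(iAs = iAs, MMA = MMA, DMA = DMA)
  if (any(v < 0)) stop("amounts must be non-negative")
  if (sum(v) <= 0) stop("composition undefined: all species are zero")
  100 * v / sum(v)
}

#' Round half away from zero
#'
#' Plain half-up rounding (2.5 -> 3), matching the convention of printed
#' integer composition tables; base `round()` rounds half to even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Total excretion-rate series
#'
#' @param series an [excretion_series()].
#' @return numeric vector of per-interval total rates (umol/hr), the
#'   elementwise sum over the three species.
#' @export
total_excretion_rate <- function(series) {
  stopifnot(inherits(series, "excretion_series"))
  rowSums(series$rates)
}

#' Write / read an excretion series as CSV
#'
#' Columns `time_hr` (interval right endpoints), `rate_iAs`, `rate_MMA`,
#' `rate_DMA` (umol/hr). The interval convention and the series start time
#' are recorded in a `#` header comment so the file round-trips.
#'
#' @param series an [excretion_series()].
#' @param path file path.
#' @return `write_excretion_csv` returns `path` invisibly;
#'   `read_excretion_csv` returns the [excretion_series()].
#' @export
write_excretion_csv <- function(series, path) {
  stopifnot(inherits(series, "excretion_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# interval urinary excretion rates (umol/hr); time_hr is the interval right endpoint",
    sprintf("# t_start=%.10g", series$sample_times[1])), con)
  df <- cbind(time_hr = series$sample_times[-1], series$rates)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_excretion_csv
#' @export
read_excretion_csv <- function(path) {
  lines <- readLines(path)
  t0_line <- grep("^# t_start=", lines, value = TRUE)
  t0 <- if (length(t0_line) > 0) {
    as.numeric(sub("^# t_start=", "", t0_line[1]))
  } else 0
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  excretion_series(c(t0, df$time_hr), df$rate_iAs, df$rate_MMA, df$rate_DMA)
}
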