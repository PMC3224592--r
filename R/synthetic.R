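#' Multiplicative measurement-noise model
#'
#' Inter-individual and assay variability in urinary arsenic data is
#' emulated with i.i.d. multiplicative lognormal factors of mean exactly 1
#' and the given coefficient of variation. `cv = 0` reproduces the
#' noiseless model output bit for bit.
#'
#' @param cv coefficient of variation, `>= 0` (default 0.05).
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @return a `noise_model` object.
#' @export
noise_model <- function(cv = 0.05, seed = 1L) {
  if (cv < 0) stop("cv must be non-negative")
  structure(list(kind = "multiplicative-lognormal", cv = cv,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# draw n mean-1 lognormal factors without disturbing the global RNG stream
noise_factors <- function(noise, n) {
  if (noise$cv == 0) return(rep(1, n))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(noise$seed)
  sdlog <- sqrt(log(1 + noise$cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic urinary excretion dataset with known truth
#'
#' Simulates the whole-body model under a dosing schedule, converts the
#' cumulative urine trajectory to interval excretion rates on the given
#' collection grid (the observable of the single- and repeated-dose
#' volunteer designs: interval urine collections over a 100-hr single-dose
#' or 14-day repeated-dose horizon), and applies multiplicative lognormal
#' noise per observation. The generating parameter set travels with the
#' data so recovery can be scored; fitting code never reads it.
#'
#' @param truth the generating `as_params` object.
#' @param schedule a [dose_schedule()].
#' @param sample_times urine collection times (hr), strictly increasing
#'   from the simulation start.
#' @param noise a [noise_model()].
#' @return list with `series` (an [excretion_series()]), `truth`,
#'   `schedule` and `noise`.
#' @export
generate_excretion_dataset <- function(truth, schedule,
                                       sample_times = seq(0, 100, by = 5),
                                       noise = noise_model()) {
  stopifnot(inherits(truth, "as_params"), inherits(noise, "noise_model"))
  # tight tolerances: the synthetic truth should be exact to well below
  # any fitting tolerance, so recovery floors reflect the data, not the
  # generator
  traj <- simulate_arsenic(truth, schedule, sample_times,
                           rtol = 1e-10, atol = 1e-12)
  series <- interval_excretion_rates(traj, sample_times)
  n <- nrow(series$rates)
  f <- matrix(noise_factors(noise, 3 * n), nrow = n)
  series$rates <- series$rates * f
  list(series = series, truth = truth, schedule = schedule, noise = noise)
}

#' Generate a synthetic in-vitro hepatocyte dataset with known truth
#'
#' Simulates the closed medium/cells system after introducing arsenite
#' into the medium at `t = 0`, samples the phase time courses on the
#' given grid, and applies multiplicative lognormal noise to every
#' concentration observation.
#'
#' @param truth the generating [hepatocyte_config()].
#' @param initial initial medium iAs concentration (uM).
#' @param sample_times sampling grid (hr) starting at 0.
#' @param noise a [noise_model()].
#' @return list with `data` (data frame of noisy phase concentrations),
#'   `clean` (the noiseless trajectory), `truth`, and `noise`.
#' @export
generate_invitro_dataset <- function(truth = hepatocyte_config(),
                                     initial = 0.1,
                                     sample_times = seq(0, 72, by = 3),
                                     noise = noise_model()) {
  stopifnot(inherits(truth, "hepatocyte_config"),
            inherits(noise, "noise_model"))
  clean <- simulate_invitro(initial, truth, sample_times)
  conc_cols <- unname(INVITRO_MAP)
  data <- clean[, c("time", conc_cols)]
  n <- nrow(data)
  f <- matrix(noise_factors(noise, n * length(conc_cols)), nrow = n)
  data[conc_cols] <- data[conc_cols] * f
  list(data = data, clean = clean, truth = truth, noise = noise)
}

#' Default synthetic triple-arm calibration datasets
#'
#' The three single-dose arms used by the staged calibration: 500 ug of
#' DMA, of MMA and of iAs, each sampled as 20 five-hour interval urine
#' collections over 0-100 hr, generated from a known truth parameter set
#' with the dietary background intake included.
#'
#' @param truth generating `as_params` (defaults to the whole-body
#'   reference set).
#' @param noise a [noise_model()] (default noiseless).
#' @param sample_times collection grid (hr).
#' @param dose dose per arm (ug).
#' @return named list of arms `DMA`, `MMA`, `iAs`, each a
#'   [generate_excretion_dataset()] result.
#' @export
synthetic_triple_arm <- function(truth = as_params("table2"),
                                 noise = noise_model(cv = 0),
                                 sample_times = seq(0, 100, by = 5),
                                 dose = 500) {
  arms <- list()
  for (sp in c("DMA", "MMA", "iAs")) {
    sched <- dose_schedule(dose_event(0, dose, sp))
    arm_noise <- noise_model(cv = noise$cv,
                             seed = noise$seed + match(sp, c("DMA", "MMA", "iAs")))
    arms[[sp]] <- generate_excretion_dataset(truth, sched, sample_times,
                                             arm_noise)
  }
  arms
}
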