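#' Convert a mass of elemental arsenic to micromoles
#'
#' @param mass micrograms of elemental arsenic, `>= 0`.
#' @return micromoles (`mass / 74.9216`).
#' @examples
#' micrograms_to_micromoles(500)  # 6.6736
#' @export
micrograms_to_micromoles <- function(mass) {
  if (any(mass < 0)) stop("mass must be non-negative")
  mass / AS_MOLAR_MASS
}

#' A single timed oral dose
#'
#' @param time dose time (hr), `>= 0`.
#' @param amount micrograms of elemental arsenic, `>= 0`.
#' @param species dosed arsenical: `"iAs"`, `"MMA"` or `"DMA"`.
#' @param absorption_k1 gut-to-blood absorption rate (1/hr) for this dose,
#'   or `NULL` to use the model parameter for the species (defaults 0.11,
#'   2 and 0.125 for iAs, MMA and DMA respectively). Arsenic trioxide is
#'   the compound behind the iAs value.
#' @return a `dose_event` object.
#' @export
dose_event <- function(time, amount, species = c("iAs", "MMA", "DMA"),
                       absorption_k1 = NULL) {
  species <- match.arg(species)
  if (time < 0) stop("dose time must be non-negative")
  if (amount < 0) stop("dose amount must be non-negative")
  if (!is.null(absorption_k1) && absorption_k1 <= 0) {
    stop("absorption_k1 must be positive")
  }
  structure(list(time = time, amount = amount, species = species,
                 absorption_k1 = absorption_k1),
            class = "dose_event")
}

#' An oral dosing schedule
#'
#' Collects timed dose events together with the delivery window (each dose
#' becomes available in the gut over a six-minute period, 0.1 hr, by
#' default), a constant dietary background intake, and an optional chronic
#' constant intake. Background and chronic intakes are inorganic arsenic.
#'
#' @param events list of [dose_event()] objects (sorted by time on
#'   construction).
#' @param delivery_window hr over which each dose enters the gut, `> 0`.
#' @param background_rate dietary background intake (ug/day), default 7.
#' @param chronic_rate chronic constant intake (ug/day), or `NULL`.
#' @return a `dose_schedule` object.
#' @export
dose_schedule <- function(events = list(), delivery_window = 0.1,
                          background_rate = 7, chronic_rate = NULL) {
  if (inherits(events, "dose_event")) events <- list(events)
  stopifnot(all(vapply(events, inherits, logical(1), "dose_event")))
  if (delivery_window <= 0) stop("delivery_window must be positive")
  if (background_rate < 0) stop("background_rate must be non-negative")
  if (!is.null(chronic_rate) && chronic_rate < 0) {
    stop("chronic_rate must be non-negative")
  }
  if (length(events) > 0) {
    events <- events[order(vapply(events, `[[`, numeric(1), "time"))]
  }
  structure(list(events = events, delivery_window = delivery_window,
                 background_rate = background_rate,
                 chronic_rate = chronic_rate),
            class = "dose_schedule")
}

#' Repeated daily dosing
#'
#' `n_days` equal doses at 24-hour spacing starting at `t = 0`, the design
#' of the repeated-dose volunteer experiments (five daily doses of 125,
#' 250, 500 or 1000 ug).
#'
#' @param daily_amount micrograms of elemental arsenic per dose.
#' @param n_days number of daily doses, `>= 1`.
#' @param species dosed arsenical.
#' @param ... passed to [dose_schedule()] (delivery window, background).
#' @return a `dose_schedule` with `n_days` events at t = 0, 24, 48, ...
#' @export
repeated_dose_schedule <- function(daily_amount, n_days,
                                   species = c("iAs", "MMA", "DMA"), ...) {
  species <- match.arg(species)
  if (n_days < 1) stop("n_days must be at least 1")
  events <- lapply(24 * (seq_len(n_days) - 1), dose_event,
                   amount = daily_amount, species = species)
  dose_schedule(events = events, ...)
}

#' Gut input-rate function of a schedule
#'
#' Returns the per-species gut input rate (uM/hr in the gut compartment)
#' as a function of time: each dose contributes
#' `amount_umol / (delivery_window * gut_volume)` over
#' `[time, time + delivery_window)` and 0 elsewhere; background and
#' chronic intakes contribute a constant inorganic-arsenic rate. The time
#' integral of the rate times the gut volume equals the total scheduled
#' micromoles.
#'
#' @param schedule a [dose_schedule()].
#' @param gut_volume gut compartment volume (L).
#' @return list with `rate`, a function `t -> c(iAs, MMA, DMA)` (uM/hr,
#'   piecewise constant), and `breakpoints`, the sorted times at which the
#'   rate jumps (integration is exact between consecutive breakpoints).
#' @export
gut_input_function <- function(schedule, gut_volume = 1) {
  stopifnot(inherits(schedule, "dose_schedule"))
  w <- schedule$delivery_window
  const_iAs <- micrograms_to_micromoles(
    schedule$background_rate + (schedule$chronic_rate %||% 0)) / 24 / gut_volume
  ev <- schedule$events
  starts <- vapply(ev, `[[`, numeric(1), "time")
  amounts <- vapply(ev, `[[`, numeric(1), "amount")
  species <- vapply(ev, `[[`, character(1), "species")
  pulse <- micrograms_to_micromoles(amounts) / (w * gut_volume)
  rate <- function(t) {
    out <- c(iAs = const_iAs, MMA = 0, DMA = 0)
    if (length(starts) > 0) {
      active <- t >= starts & t < starts + w
      for (i in which(active)) out[species[i]] <- out[species[i]] + pulse[i]
    }
    out
  }
  list(rate = rate,
       breakpoints = sort(unique(c(starts, starts + w))))
}

#' Micromoles delivered by a schedule up to a time
#'
#' Bookkeeping companion of [gut_input_function()]: the exact cumulative
#' molar input (events, pro-rated within their delivery window, plus
#' background and chronic contributions) up to time `t`. Used by the
#' conservation checks.
#'
#' @param schedule a [dose_schedule()].
#' @param t time (hr).
#' @return micromoles delivered on `[0, t]`.
#' @export
schedule_delivered_micromoles <- function(schedule, t) {
  stopifnot(inherits(schedule, "dose_schedule"))
  w <- schedule$delivery_window
  const <- micrograms_to_micromoles(
    schedule$background_rate + (schedule$chronic_rate %||% 0)) / 24
  ev <- schedule$events
  delivered <- const * t
  for (e in ev) {
    frac <- min(max((t - e$time) / w, 0), 1)
    delivered <- delivered + frac * micrograms_to_micromoles(e$amount)
  }
  delivered
}

# effective per-species absorption constants: model parameters, overridden
# by any absorption_k1 carried on the schedule's events (must be consistent
# within a species)
effective_absorption <- function(p, schedule) {
  k <- c(iAs = p$k1, MMA = p$k1_MMA, DMA = p$k1_DMA)
  for (e in schedule$events) {
    if (!is.null(e$absorption_k1)) {
      sp <- e$species
      if (!is.null(attr(k, "set")) && sp %in% attr(k, "set") &&
          k[sp] != e$absorption_k1) {
        stop("conflicting absorption_k1 values for species ", sp)
      }
      k[sp] <- e$absorption_k1
      attr(k, "set") <- union(attr(k, "set"), sp)
    }
  }
  attr(k, "set") <- NULL
  k
}
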