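# Internal: precompute the constants the right-hand side needs.
# k_abs is the effective per-species gut absorption vector (1/hr).
rhs_constants <- function(p, k_abs = NULL) {
  r <- volume_ratios(p)
  samf <- sam_modulation(p$SAM, p$Km_SAM, p$alpha)
  if (is.null(k_abs)) k_abs <- c(iAs = p$k1, MMA = p$k1_MMA, DMA = p$k1_DMA)
  list(
    k1i = k_abs[["iAs"]], k1m = k_abs[["MMA"]], k1d = k_abs[["DMA"]],
    k2 = p$k2, k_2 = p$k_2, k3 = p$k3, k_3 = p$k_3, k4 = p$k4, k_4 = p$k_4,
    k5 = p$k5, k_5 = p$k_5, k6 = p$k6, k7 = p$k7, k8 = p$k8,
    k9 = p$k9, k_9 = p$k_9, k10 = p$k10, k_10 = p$k_10,
    rgb = r[["rgb"]], rlb = r[["rlb"]], rsb = r[["rsb"]],
    vol_blood = p$vol_blood,
    vm1 = p$upregulation * p$Vmax1 * samf,
    vm2 = p$upregulation * p$Vmax2 * samf,
    Km1 = p$Km1, Km2 = p$Km2,
    Ksi = p$Ksi, Kip = p$Ki_prod, Kii = p$Ki_iAs
  )
}

# Internal: pack constants + per-segment input rates into the flat
# parameter vector consumed by the compiled RHS (src/asmethyl_model.c);
# the order here and there must agree.
rhs_parms_vector <- function(pc, input) {
  c(pc$k1i, pc$k1m, pc$k1d, pc$k2, pc$k_2, pc$k3, pc$k_3, pc$k4, pc$k_4,
    pc$k5, pc$k_5, pc$k6, pc$k7, pc$k8, pc$k9, pc$k_9, pc$k10, pc$k_10,
    pc$rgb, pc$rlb, pc$rsb, pc$vol_blood, pc$vm1, pc$vm2,
    pc$Km1, pc$Km2, pc$Ksi, pc$Kip, pc$Kii,
    input[1], input[2], input[3])
}

# Internal: the right-hand side on the 15-element state vector, by index.
# `input` is the per-species gut input rate c(iAs, MMA, DMA) in uM/hr.
# Every flux appears once as a loss and once (volume-converted) as a gain,
# so the volume-weighted mole balance closes exactly by construction.
rhs_eval <- function(y, pc, input) {
  LiAs <- max(y[8], 0)
  LMMA <- max(y[10], 0)
  V1 <- pc$vm1 * LiAs /
    ((pc$Km1 + LiAs) * (1 + LiAs / pc$Ksi) * (1 + LMMA / pc$Kip))
  V2 <- pc$vm2 * LMMA / ((pc$Km2 + LMMA) * (1 + LiAs / pc$Kii))
  c(
    input[1] - pc$k1i * y[1],
    input[2] - pc$k1m * y[2],
    input[3] - pc$k1d * y[3],
    pc$k1i * pc$rgb * y[1] + pc$k_2 * pc$rsb * y[7] + pc$k_3 * pc$rlb * y[8] -
      (pc$k3 + pc$k2 + pc$k6) * y[4],
    pc$k1m * pc$rgb * y[2] + pc$k_4 * pc$rlb * y[10] -
      (pc$k4 + pc$k7) * y[5],
    pc$k1d * pc$rgb * y[3] + pc$k_5 * pc$rlb * y[11] -
      (pc$k5 + pc$k8) * y[6],
    pc$k2 / pc$rsb * y[4] - pc$k_2 * y[7],
    pc$k3 / pc$rlb * y[4] - pc$k_3 * y[8] + pc$k_9 * y[9] - pc$k9 * y[8] - V1,
    pc$k9 * y[8] - pc$k_9 * y[9],
    pc$k4 / pc$rlb * y[5] - pc$k_4 * y[10] + V1 - V2,
    pc$k5 / pc$rlb * y[6] - pc$k_5 * y[11] + V2 + pc$k_10 * y[12] -
      pc$k10 * y[11],
    pc$k10 * y[11] - pc$k_10 * y[12],
    pc$vol_blood * pc$k6 * y[4],
    pc$vol_blood * pc$k7 * y[5],
    pc$vol_blood * pc$k8 * y[6]
  )
}

#' Right-hand side of the whole-body model
#'
#' Time derivative of every state variable given the current state and a
#' constant gut input rate. All transport and excretion steps are linear;
#' the two methylation steps follow [v1_velocity()] and [v2_velocity()].
#' Volume ratios convert fluxes between compartments of different size,
#' and the urine derivatives carry the blood-volume factor so that the
#' urinary variables accumulate micromoles. The identity
#' `sum(volume * dC/dt) + dU/dt = input_rate * gut_volume`
#' (total moles in equals total moles accounted) holds exactly for any
#' state.
#'
#' @param state named state vector (see [arsenic_state()]), non-negative.
#' @param p an `as_params` object.
#' @param input_rate gut input rate (uM/hr): a single number (inorganic
#'   arsenic) or a named vector `c(iAs=, MMA=, DMA=)`.
#' @return named vector of time derivatives (uM/hr; urine entries
#'   umol/hr).
#' @export
arsenic_derivatives <- function(state, p, input_rate = 0) {
  if (any(state < 0)) stop("state fields must be non-negative")
  input <- expand_input(input_rate)
  d <- rhs_eval(as.numeric(state[STATE_NAMES]), rhs_constants(p), input)
  stats::setNames(d, STATE_NAMES)
}

expand_input <- function(input_rate) {
  if (length(input_rate) == 1 && is.null(names(input_rate))) {
    return(c(input_rate, 0, 0))
  }
  out <- c(iAs = 0, MMA = 0, DMA = 0)
  out[names(input_rate)] <- input_rate
  unname(out)
}

#' Simulate the whole-body model under a dosing schedule
#'
#' Integrates the model with the stiff-capable `lsoda` solver. The gut
#' input of a [dose_schedule()] is piecewise constant (rectangular pulses
#' over the delivery window plus constant background/chronic terms), so
#' the integration is restarted at every input breakpoint; no pulse can be
#' stepped over.
#'
#' @param p an `as_params` object.
#' @param schedule a [dose_schedule()]; defaults to no doses and no
#'   background.
#' @param times strictly increasing output time grid (hr), starting at the
#'   initial time.
#' @param initial initial state ([arsenic_state()]); defaults to all zero.
#' @param rtol,atol relative/absolute integration tolerances.
#' @return an `as_trajectory`: a data frame with column `time` and one
#'   column per state field, with the parameters and schedule attached as
#'   attributes.
#' @export
simulate_arsenic <- function(p, schedule = dose_schedule(background_rate = 0),
                             times, initial = arsenic_state(),
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "as_params"), inherits(schedule, "dose_schedule"))
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing with at least two points")
  }
  if (any(initial < 0)) stop("initial state must be non-negative")
  inp <- gut_input_function(schedule, p$vol_gut)
  pc <- rhs_constants(p, effective_absorption(p, schedule))
  t0 <- times[1]; t1 <- times[length(times)]
  bounds <- sort(unique(c(t0, t1, inp$breakpoints[inp$breakpoints > t0 &
                                                    inp$breakpoints < t1])))
  y <- as.numeric(initial[STATE_NAMES])
  rows <- list(c(t0, y))
  for (i in seq_len(length(bounds) - 1)) {
    a <- bounds[i]; b <- bounds[i + 1]
    seg_times <- unique(c(a, times[times > a & times < b], b))
    rate <- inp$rate(a)
    sol <- deSolve::lsoda(y, seg_times, func = "asmethyl_derivs",
                          dllname = "asmethyl", initfunc = "asmethyl_initmod",
                          parms = rhs_parms_vector(pc, rate),
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE integration failed on [", a, ", ", b, "] hr (lsoda istate ",
           attr(sol, "istate")[1], ")")
    }
    keep <- seg_times %in% times & seg_times > a
    for (j in which(keep)) rows[[length(rows) + 1]] <- sol[j, ]
    y <- as.numeric(sol[nrow(sol), -1])
  }
  m <- do.call(rbind, rows)
  vals <- m[, -1, drop = FALSE]
  neg <- vals < 0
  # negatives within solver noise (order atol) are clipped; anything larger
  # indicates a misconfigured integration and is an error
  if (any(vals[neg] < -10 * atol)) {
    stop("integration produced negative concentrations beyond tolerance; ",
         "min = ", min(vals))
  }
  vals[neg] <- 0
  out <- data.frame(time = m[, 1], vals)
  names(out) <- c("time", STATE_NAMES)
  structure(out, class = c("as_trajectory", "data.frame"),
            params = p, schedule = schedule)
}

#' Steady state under constant gut input
#'
#' Finds the state at which all non-urine derivatives vanish for a
#' constant input rate (chronic exposure). The system is first integrated
#' over a long horizon with a derivative-norm stopping rule, then the
#' root of the reduced (non-urine) right-hand side is polished by damped
#' Newton iteration with a finite-difference Jacobian, cross-checking the
#' integration result. At the returned state the total urinary molar
#' excretion rate balances the molar input rate.
#'
#' @param p an `as_params` object.
#' @param constant_input constant gut input rate (uM/hr); scalar iAs or
#'   named per-species vector.
#' @param tol convergence tolerance on the derivative norm (uM/hr).
#' @param horizon maximum integration horizon (hr).
#' @return steady state as an [arsenic_state()] vector (urine fields 0),
#'   with attributes `residual` (max abs non-urine derivative) and
#'   `converged`.
#' @export
steady_state <- function(p, constant_input, tol = 1e-10, horizon = 1e4) {
  stopifnot(inherits(p, "as_params"))
  input <- expand_input(constant_input)
  if (sum(input) <= 0) stop("constant_input must be positive")
  pc <- rhs_constants(p)
  y <- numeric(15)
  t <- 0; chunk <- 2000
  repeat {
    sol <- deSolve::lsoda(y, c(0, chunk), func = "asmethyl_derivs",
                          dllname = "asmethyl", initfunc = "asmethyl_initmod",
                          parms = rhs_parms_vector(pc, input),
                          rtol = 1e-10, atol = 1e-12, maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0) stop("steady-state integration failed")
    y <- as.numeric(sol[2, -1])
    t <- t + chunk
    res <- max(abs(rhs_eval(y, pc, input)[1:12]))
    if (res < tol || t >= horizon) break
  }
  # Newton polish on the 12 non-urine states
  f12 <- function(z) rhs_eval(c(z, 0, 0, 0), pc, input)[1:12]
  z <- y[1:12]
  converged <- FALSE
  # iterate to near machine level: slow exchange modes amplify a
  # derivative residual r into a state offset r/lambda (lambda ~ 0.01/hr),
  # so stopping at the integration residual would leave ~1e-8 state error
  for (it in 1:30) {
    fz <- f12(z)
    if (max(abs(fz)) < 1e-14 * max(1, max(abs(z)))) { converged <- TRUE; break }
    J <- matrix(0, 12, 12)
    for (j in 1:12) {
      h <- max(abs(z[j]), 1e-6) * 1e-7
      zp <- z; zp[j] <- zp[j] + h
      J[, j] <- (f12(zp) - fz) / h
    }
    step <- tryCatch(solve(J, fz), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      znew <- z - lambda * step
      if (all(znew >= 0) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    z <- pmax(znew, 0)
  }
  res <- max(abs(f12(z)))
  if (res >= tol) {
    if (max(abs(rhs_eval(y, pc, input)[1:12])) < tol) {
      z <- y[1:12]; res <- max(abs(f12(z))); converged <- TRUE
    } else {
      stop("steady state did not converge: residual ", format(res),
           " uM/hr after ", t, " hr horizon")
    }
  }
  structure(stats::setNames(c(z, 0, 0, 0), STATE_NAMES),
            residual = res, converged = TRUE)
}

#' Urinary excretion rates at a state
#'
#' The instantaneous molar excretion rates into urine,
#' `vol_blood * k * [blood species]` (umol/hr) for the three arsenicals.
#' At steady state under constant input their sum equals the molar input
#' rate.
#'
#' @param state a state vector.
#' @param p an `as_params` object.
#' @return named vector `c(iAs=, MMA=, DMA=)` in umol/hr.
#' @export
urinary_excretion_rates <- function(state, p) {
  c(iAs = p$vol_blood * p$k6 * state[["BiAs"]],
    MMA = p$vol_blood * p$k7 * state[["BMMAs"]],
    DMA = p$vol_blood * p$k8 * state[["BDMAs"]])
}
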