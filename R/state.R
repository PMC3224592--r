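#' Model state vector
#'
#' Constructs the named state vector of the whole-body model. Body
#' compartments are concentrations (uM): `gut`, `gut_MMA`, `gut_DMA`
#' (arsenicals awaiting absorption, one gut pool per dosed species),
#' `BiAs`, `BMMAs`, `BDMAs` (blood), `bodystore` (iAs reversibly bound in
#' non-liver tissues), `LiAs`, `LiAs_store`, `LMMAs`, `LDMAs`,
#' `LDMAs_store` (liver free and protein-bound pools). The urinary
#' variables `UiAs`, `UMMAs`, `UDMAs` are cumulative amounts in micromoles
#' (the blood-volume factor in their differential equations converts
#' concentration flux to molar flux), so trajectories can be compared
#' directly to interval urine collections.
#'
#' @param ... named initial values; unnamed fields default to 0.
#' @return named numeric vector of length 15 in canonical order.
#' @examples
#' arsenic_state(gut = 6.67)  # a 500 ug oral dose fully in the gut, 1 L
#' @export
arsenic_state <- function(...) {
  vals <- c(...)
  s <- stats::setNames(numeric(length(STATE_NAMES)), STATE_NAMES)
  if (length(vals) > 0) {
    bad <- setdiff(names(vals), STATE_NAMES)
    if (length(bad) > 0 || is.null(names(vals))) {
      stop("unknown state field(s): ", paste(bad, collapse = ", "))
    }
    if (any(vals < 0)) stop("state fields must be non-negative")
    s[names(vals)] <- vals
  }
  s
}

#' Total arsenic in the system (micromoles)
#'
#' Volume-weighted sum of all compartment concentrations plus the
#' cumulative urine amounts. Because methylation converts species
#' one-to-one and every transport flux is volume-consistent, this total
#' minus the cumulative molar input is conserved along any trajectory.
#'
#' @param state a state vector (or trajectory row) named as
#'   [arsenic_state()].
#' @param p an `as_params` object supplying the compartment volumes.
#' @return total micromoles of arsenic.
#' @export
total_micromoles <- function(state, p) {
  g <- state[["gut"]] + state[["gut_MMA"]] + state[["gut_DMA"]]
  b <- state[["BiAs"]] + state[["BMMAs"]] + state[["BDMAs"]]
  l <- state[["LiAs"]] + state[["LiAs_store"]] + state[["LMMAs"]] +
    state[["LDMAs"]] + state[["LDMAs_store"]]
  u <- state[["UiAs"]] + state[["UMMAs"]] + state[["UDMAs"]]
  p$vol_gut * g + p$vol_blood * b + p$vol_store * state[["bodystore"]] +
    p$vol_liver * l + u
}
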