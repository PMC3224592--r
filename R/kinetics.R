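#' SAM modulation factor of the methylation velocities
#'
#' Both AS3MT methylation steps consume a methyl group from
#' S-adenosylmethionine (SAM), so both velocities carry a saturable factor
#' `alpha * SAM / (Km_SAM + SAM)`. The normalisation constant `alpha` is
#' chosen so the factor equals exactly 1 at the declared normal liver SAM
#' concentration (see [alpha_for_normal_sam()]); below-normal SAM (folate
#' deficiency) then slows both methylation steps proportionally.
#'
#' @param SAM liver SAM concentration (uM), `>= 0`.
#' @param Km_SAM Michaelis constant of AS3MT for SAM (uM), default 11.8.
#' @param alpha normalisation constant, `> 0`.
#' @return dimensionless factor, 0 at `SAM = 0`, strictly increasing in
#'   `SAM`.
#' @examples
#' sam_modulation(60, 11.8, alpha_for_normal_sam(60, 11.8)) # exactly 1
#' @export
sam_modulation <- function(SAM, Km_SAM = 11.8, alpha = 1.1967) {
  if (any(SAM < 0)) stop("SAM must be non-negative")
  if (any(Km_SAM <= 0)) stop("Km_SAM must be positive")
  if (any(alpha <= 0)) stop("alpha must be positive")
  alpha * SAM / (Km_SAM + SAM)
}

#' Normalisation constant for the SAM factor
#'
#' Solves `alpha * S / (Km_SAM + S) = 1` for `alpha` at the normal SAM
#' concentration `S`, i.e. `alpha = (Km_SAM + S) / S`. With `Km_SAM =
#' 11.8` uM this gives 1.1967 for a normal SAM of 60 uM and 1.2950 for
#' 40 uM.
#'
#' @param SAM_normal normal liver SAM concentration (uM), `> 0`.
#' @param Km_SAM Michaelis constant for SAM (uM), `> 0`.
#' @return the constant `alpha` (dimensionless).
#' @export
alpha_for_normal_sam <- function(SAM_normal, Km_SAM = 11.8) {
  if (any(SAM_normal <= 0)) stop("SAM_normal must be strictly positive")
  if (any(Km_SAM <= 0)) stop("Km_SAM must be positive")
  (Km_SAM + SAM_normal) / SAM_normal
}

#' Velocity of the first methylation step (liver iAs -> liver MMA)
#'
#' Michaelis-Menten kinetics in liver inorganic arsenic with substrate
#' inhibition (the `(1 + LiAs/Ksi)` factor, which makes the velocity
#' non-monotone with an interior maximum at `sqrt(Km1 * Ksi)`) and
#' product inhibition by liver MMA (the `(1 + LMMAs/Ki_prod)` factor),
#' scaled by the AS3MT expression multiplier and the SAM factor:
#'
#' `V1 = upregulation * Vmax1 * LiAs /
#'   ((Km1 + LiAs) * (1 + LiAs/Ksi) * (1 + LMMAs/Ki_prod)) *
#'   alpha * SAM / (Km_SAM + SAM)`
#'
#' @param LiAs liver inorganic arsenic (uM), `>= 0`.
#' @param LMMAs liver monomethyl arsenic (uM), `>= 0`.
#' @param p an `as_params` object (or list with the methylation fields).
#' @return methylation rate (uM/hr), non-negative.
#' @export
v1_velocity <- function(LiAs, LMMAs, p) {
  if (any(LiAs < 0) || any(LMMAs < 0)) {
    stop("concentrations must be non-negative")
  }
  samf <- sam_modulation(p$SAM, p$Km_SAM, p$alpha)
  p$upregulation * p$Vmax1 * LiAs /
    ((p$Km1 + LiAs) * (1 + LiAs / p$Ksi) * (1 + LMMAs / p$Ki_prod)) * samf
}

#' Velocity of the second methylation step (liver MMA -> liver DMA)
#'
#' Michaelis-Menten kinetics in liver MMA, inhibited by liver inorganic
#' arsenic, scaled by the AS3MT expression multiplier and the SAM factor:
#'
#' `V2 = upregulation * Vmax2 * LMMAs /
#'   ((Km2 + LMMAs) * (1 + LiAs/Ki_iAs)) * alpha * SAM / (Km_SAM + SAM)`
#'
#' Monotone increasing in `LMMAs`, monotone decreasing in `LiAs`.
#'
#' @param LMMAs liver monomethyl arsenic (uM), `>= 0`.
#' @param LiAs liver inorganic arsenic (uM), `>= 0`.
#' @param p an `as_params` object.
#' @return methylation rate (uM/hr), non-negative.
#' @export
v2_velocity <- function(LMMAs, LiAs, p) {
  if (any(LiAs < 0) || any(LMMAs < 0)) {
    stop("concentrations must be non-negative")
  }
  samf <- sam_modulation(p$SAM, p$Km_SAM, p$alpha)
  p$upregulation * p$Vmax2 * LMMAs /
    ((p$Km2 + LMMAs) * (1 + LiAs / p$Ki_iAs)) * samf
}
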