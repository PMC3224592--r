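#' In-vitro hepatocyte configuration
#'
#' Parameterises the reduced medium-plus-cells variant of the model for
#' cultured human hepatocyte experiments: the urine compartment, gut
#' input and whole-body store are removed (`k1`, `k6`, `k7`, `k8`, `k10`,
#' `k_10` are identically 0), "blood" becomes the culture medium and
#' "liver" the cells, and the cells/medium volume ratio `rcm` replaces the
#' liver/blood ratio. A medium storage pool (collagen-bound iAs on the
#' well plate, rate constants `k2`/`k_2`) replaces the body store with a
#' store/medium volume ratio of 1, and the cells keep an iAs store
#' (`k9`/`k_9`) but no DMA store. Default volumes are the 0.5 ml wells
#' with 0.25e6 cells of 2e-9 ml each (0.0005 ml, ratio 0.001); with
#' volumes in ml and concentrations in uM, phase totals are in nmol.
#' Methylation Km/Ki values match the whole-body model; Vmax values are
#' the cultured-cell ones (22 and 2.75 uM/hr).
#'
#' @param medium_volume well medium volume (ml).
#' @param cell_volume total cell volume (ml).
#' @param k2,k_2 medium free iAs <-> medium store (1/hr).
#' @param k3,k_3 iAs medium <-> cells (1/hr).
#' @param k4,k_4 MMA medium <-> cells (1/hr).
#' @param k5,k_5 DMA medium <-> cells (1/hr).
#' @param k9,k_9 cell iAs <-> cell iAs store (1/hr).
#' @param Vmax1,Vmax2 methylation maximal rates (uM/hr).
#' @param Km1,Km2,Ki_iAs methylation constants (uM).
#' @param SAM,Km_SAM,alpha SAM factor settings (normal SAM by default, so
#'   the factor is 1).
#' @param inhibition_convention assignment of the 1.26/40 uM inhibition
#'   constants of step 1 (see [as_params()]).
#' @param k1,k6,k7,k8,k10,k_10 must remain 0; supplying a nonzero value is
#'   a configuration error.
#' @return a `hepatocyte_config` object.
#' @export
hepatocyte_config <- function(medium_volume = 0.5, cell_volume = 5e-4,
                              k2 = 0.4, k_2 = 0.07,
                              k3 = 0.45, k_3 = 0.5,
                              k4 = 0.2, k_4 = 0.05,
                              k5 = 0.015, k_5 = 0.2,
                              k9 = 0.3, k_9 = 0.05,
                              Vmax1 = 22, Vmax2 = 2.75,
                              Km1 = 4.6, Km2 = 4.6, Ki_iAs = 40,
                              SAM = 60, Km_SAM = 11.8,
                              alpha = alpha_for_normal_sam(60, 11.8),
                              inhibition_convention = c("table", "text"),
                              k1 = 0, k6 = 0, k7 = 0, k8 = 0,
                              k10 = 0, k_10 = 0) {
  inhibition_convention <- match.arg(inhibition_convention)
  forbidden <- c(k1 = k1, k6 = k6, k7 = k7, k8 = k8, k10 = k10, k_10 = k_10)
  if (any(forbidden != 0)) {
    stop("in-vitro configuration requires zero ",
         paste(names(forbidden)[forbidden != 0], collapse = ", "),
         " (no gut input, no urine, no cell DMA store)")
  }
  if (medium_volume <= 0 || cell_volume <= 0) {
    stop("volumes must be positive")
  }
  inh <- if (inhibition_convention == "table") c(Ksi = 40, Ki_prod = 1.26)
         else                                  c(Ksi = 1.26, Ki_prod = 40)
  structure(list(
    medium_volume = medium_volume, cell_volume = cell_volume,
    rcm = cell_volume / medium_volume,
    k2 = k2, k_2 = k_2, k3 = k3, k_3 = k_3, k4 = k4, k_4 = k_4,
    k5 = k5, k_5 = k_5, k9 = k9, k_9 = k_9,
    Vmax1 = Vmax1, Vmax2 = Vmax2, Km1 = Km1, Km2 = Km2,
    Ksi = unname(inh["Ksi"]), Ki_prod = unname(inh["Ki_prod"]),
    Ki_iAs = Ki_iAs, SAM = SAM, Km_SAM = Km_SAM, alpha = alpha,
    convention = inhibition_convention
  ), class = "hepatocyte_config")
}

#' Core-model parameter set for the in-vitro variant
#'
#' Maps a [hepatocyte_config()] onto the whole-body parameter structure:
#' medium for blood, cells for liver, the medium store (ratio 1) in the
#' body-store slot, and zeroed gut/urine/DMA-store pathways. The mole
#' balance then closes over medium + medium store + cells + cell store
#' (the system is closed).
#'
#' @param cfg a `hepatocyte_config`.
#' @return an `as_params` object with `context = "invitro"` (volumes in
#'   ml; phase totals in nmol).
#' @export
configure_invitro <- function(cfg) {
  stopifnot(inherits(cfg, "hepatocyte_config"))
  p <- structure(list(
    vol_gut = 1,                       # inert: no gut input pathway
    vol_blood = cfg$medium_volume,
    vol_liver = cfg$cell_volume,
    vol_store = cfg$medium_volume,     # medium store, store/medium ratio 1
    k1 = 0, k1_MMA = 0, k1_DMA = 0,
    k2 = cfg$k2, k_2 = cfg$k_2,
    k3 = cfg$k3, k_3 = cfg$k_3,
    k4 = cfg$k4, k_4 = cfg$k_4,
    k5 = cfg$k5, k_5 = cfg$k_5,
    k6 = 0, k7 = 0, k8 = 0,
    k9 = cfg$k9, k_9 = cfg$k_9,
    k10 = 0, k_10 = 0,
    Vmax1 = cfg$Vmax1, Vmax2 = cfg$Vmax2, Km1 = cfg$Km1, Km2 = cfg$Km2,
    Ksi = cfg$Ksi, Ki_prod = cfg$Ki_prod, Ki_iAs = cfg$Ki_iAs,
    Km_SAM = cfg$Km_SAM, alpha = cfg$alpha, SAM = cfg$SAM,
    upregulation = 1
  ), class = "as_params", convention = cfg$convention, context = "invitro")
  validate_params(p)
}

# phase-qualified names for the in-vitro state mapping
INVITRO_MAP <- c(
  BiAs = "medium_iAs", BMMAs = "medium_MMA", BDMAs = "medium_DMA",
  bodystore = "medium_iAs_store",
  LiAs = "cell_iAs", LiAs_store = "cell_iAs_store",
  LMMAs = "cell_MMA", LDMAs = "cell_DMA", LDMAs_store = "cell_DMA_store"
)

#' Simulate the in-vitro hepatocyte experiment
#'
#' Arsenite is introduced into the medium at `t = 0` and the closed
#' medium/cells system evolves under the [hepatocyte_config()] kinetics.
#' Because the cells/medium volume ratio is 0.001, cell concentrations
#' can exceed medium concentrations by orders of magnitude while holding
#' a small fraction of the total moles; the returned trajectory therefore
#' carries both concentration columns (uM) and phase-total columns
#' (nmol).
#'
#' @param initial_medium_iAs initial medium iAs concentration (uM),
#'   `>= 0`.
#' @param cfg a `hepatocyte_config`.
#' @param times strictly increasing output grid (hr) starting at 0.
#' @param rtol,atol integration tolerances.
#' @return a data frame (class `invitro_trajectory`) with `time`,
#'   phase-qualified concentration columns (`medium_iAs`,
#'   `medium_iAs_store`, `medium_MMA`, `medium_DMA`, `cell_iAs`,
#'   `cell_iAs_store`, `cell_MMA`, `cell_DMA`), and `medium_total_nmol`,
#'   `cell_total_nmol`, `total_nmol`.
#' @export
simulate_invitro <- function(initial_medium_iAs, cfg = hepatocyte_config(),
                             times = seq(0, 72, by = 0.5),
                             rtol = 1e-8, atol = 1e-10) {
  if (initial_medium_iAs < 0) stop("initial concentration must be non-negative")
  p <- configure_invitro(cfg)
  traj <- simulate_arsenic(p, dose_schedule(background_rate = 0), times,
                           initial = arsenic_state(BiAs = initial_medium_iAs),
                           rtol = rtol, atol = atol)
  out <- data.frame(time = traj$time)
  for (nm in names(INVITRO_MAP)) out[[INVITRO_MAP[[nm]]]] <- traj[[nm]]
  out$medium_total_nmol <- p$vol_blood *
    (out$medium_iAs + out$medium_iAs_store + out$medium_MMA + out$medium_DMA)
  out$cell_total_nmol <- p$vol_liver *
    (out$cell_iAs + out$cell_iAs_store + out$cell_MMA + out$cell_DMA)
  out$total_nmol <- out$medium_total_nmol + out$cell_total_nmol
  structure(out, class = c("invitro_trajectory", "data.frame"),
            params = p, config = cfg)
}
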