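## Biophysical building blocks: multicompartment pyramidal cell (PC), point
## basket cell (BC), and the three synapse kinds.

#' Cylindrical compartment geometry
#'
#' @param length_um,diameter_um cylinder dimensions (micrometres).
#' @param n_segments number of segments the compartment is subdivided into
#'   for spatial integration accuracy (3 for every PC compartment).
#' @param axial_resistivity_ohm_cm axial resistivity (Ohm cm).
#' @param specific_capacitance_uF_cm2 membrane capacitance (uF/cm^2).
#' @return list of class `"compartment_geometry"`.
#' @export
compartment_geometry <- function(length_um, diameter_um, n_segments = 3L,
                                 axial_resistivity_ohm_cm = 150,
                                 specific_capacitance_uF_cm2 = 1) {
  assert_positive(length_um, "length_um")
  assert_positive(diameter_um, "diameter_um")
  stopifnot(n_segments >= 1)
  structure(list(length_um = length_um, diameter_um = diameter_um,
                 n_segments = as.integer(n_segments),
                 axial_resistivity_ohm_cm = axial_resistivity_ohm_cm,
                 specific_capacitance_uF_cm2 = specific_capacitance_uF_cm2),
            class = "compartment_geometry")
}

#' Surface area of one segment of a compartment (cm^2)
#' @param geom a [compartment_geometry()].
#' @export
segment_area_cm2 <- function(geom) {
  pi * (geom$diameter_um * 1e-4) * (geom$length_um * 1e-4 / geom$n_segments)
}

#' Axial resistance of half a segment (MOhm)
#' @param geom a [compartment_geometry()].
#' @export
segment_half_axial_Mohm <- function(geom) {
  L_half <- geom$length_um * 1e-4 / geom$n_segments / 2          # cm
  area <- pi * (geom$diameter_um * 1e-4)^2 / 4                   # cm^2
  geom$axial_resistivity_ohm_cm * L_half / area * 1e-6
}

pc_compartment_names <- function() {
  c("basal", "soma", "proximal", "middle", "distal")
}

#' Pyramidal-cell parameter set
#'
#' Five cylindrical compartments (basal dendrite, soma, and a
#' proximal/middle/distal apical chain), each subdivided into three
#' segments. Somatic transient Na and delayed-rectifier K generate spikes;
#' the dendrites carry the same channels at lower density (active dendrites)
#' plus a hyperpolarization-activated current that grows towards the distal
#' apical tuft. Densities in mS/cm^2, reversals in mV. The defaults are the
#' calibrated values used by the network motifs.
#'
#' @param geometry named list of 5 [compartment_geometry()] objects.
#' @param densities 5 x 4 matrix (rows = compartments) with columns
#'   `gL`, `gNa`, `gK`, `gH` (mS/cm^2).
#' @param e_leak,e_na,e_k,e_h reversal potentials (mV).
#' @return list of class `"pyramidal_cell_params"`.
#' @export
pyramidal_cell_params <- function(
    geometry = list(
      basal    = compartment_geometry(200, 3,   axial_resistivity_ohm_cm = 300),
      soma     = compartment_geometry(20, 20,   axial_resistivity_ohm_cm = 300),
      proximal = compartment_geometry(250, 2,   axial_resistivity_ohm_cm = 300),
      middle   = compartment_geometry(300, 1.6, axial_resistivity_ohm_cm = 300),
      distal   = compartment_geometry(350, 1.3, axial_resistivity_ohm_cm = 300)),
    densities = rbind(
      basal    = c(gL = 0.1, gNa = 10,  gK = 8,  gH = 0),
      soma     = c(gL = 0.1, gNa = 100, gK = 80, gH = 0),
      proximal = c(gL = 0.1, gNa = 10,  gK = 8,  gH = 0.05),
      middle   = c(gL = 0.1, gNa = 10,  gK = 8,  gH = 0.1),
      distal   = c(gL = 0.1, gNa = 10,  gK = 8,  gH = 0.2)),
    e_leak = -67, e_na = 50, e_k = -100, e_h = -30) {
  stopifnot(identical(names(geometry), pc_compartment_names()),
            identical(rownames(densities), pc_compartment_names()),
            all(densities >= 0))
  for (g in geometry) {
    stopifnot(inherits(g, "compartment_geometry"), g$n_segments == 3L)
  }
  structure(list(geometry = geometry, densities = densities,
                 e_leak = e_leak, e_na = e_na, e_k = e_k, e_h = e_h),
            class = "pyramidal_cell_params")
}

#' Basket-cell parameter set
#'
#' Single-compartment fast-spiking point neuron (Wang-Buzsaki kinetics).
#' Dendritic integration is not modelled explicitly; instead a fixed 1 ms
#' input delay from external drivers stands in for the (fast) dendritic
#' transmission time of basket cells.
#'
#' @param geometry a [compartment_geometry()] (single segment).
#' @param densities named vector `gL`, `gNa`, `gK` (mS/cm^2).
#' @param e_leak,e_na,e_k reversal potentials (mV).
#' @param input_delay_ms fixed delay from external drivers (ms).
#' @return list of class `"basket_cell_params"`.
#' @export
basket_cell_params <- function(
    geometry = compartment_geometry(15, 15, n_segments = 1L),
    densities = c(gL = 0.1, gNa = 35, gK = 9),
    e_leak = -62, e_na = 55, e_k = -90, input_delay_ms = 1) {
  stopifnot(inherits(geometry, "compartment_geometry"),
            geometry$n_segments == 1L, all(densities >= 0))
  structure(list(geometry = geometry, densities = densities,
                 e_leak = e_leak, e_na = e_na, e_k = e_k,
                 input_delay_ms = input_delay_ms),
            class = "basket_cell_params")
}

#' Double-exponential synapse parameters
#'
#' @param kind `"AMPA"`, `"NMDA"` or `"GABA_A"`.
#' @param tau_rise_ms,tau_decay_ms kinetics (ms), `tau_decay > tau_rise`.
#' @param reversal_mV synaptic reversal potential.
#' @param weight_uS peak conductance (uS).
#' @param mg_mM magnesium concentration for the NMDA block (mM).
#' @return list of class `"synapse_params"`.
#' @export
synapse_params <- function(kind = c("AMPA", "NMDA", "GABA_A"),
                           tau_rise_ms = NULL, tau_decay_ms = NULL,
                           reversal_mV = NULL, weight_uS = 1e-3, mg_mM = 1) {
  kind <- match.arg(kind)
  defaults <- list(AMPA   = list(0.5, 3, 0),
                   NMDA   = list(2, 100, 0),
                   GABA_A = list(0.5, 5, -75))[[kind]]
  tau_rise_ms <- tau_rise_ms %||% defaults[[1]]
  tau_decay_ms <- tau_decay_ms %||% defaults[[2]]
  reversal_mV <- reversal_mV %||% defaults[[3]]
  if (tau_rise_ms <= 0) stop("tau_rise must be positive", call. = FALSE)
  if (tau_decay_ms == tau_rise_ms) {
    stop("degenerate kinetics: tau_rise equals tau_decay", call. = FALSE)
  }
  if (tau_decay_ms < tau_rise_ms) {
    stop("tau_decay must exceed tau_rise", call. = FALSE)
  }
  if (weight_uS < 0) stop("weight must be non-negative", call. = FALSE)
  if (mg_mM < 0) stop("mg concentration must be non-negative", call. = FALSE)
  structure(list(kind = kind, tau_rise_ms = tau_rise_ms,
                 tau_decay_ms = tau_decay_ms, reversal_mV = reversal_mV,
                 weight_uS = weight_uS, mg_mM = mg_mM),
            class = "synapse_params")
}

#' Voltage-dependent NMDA magnesium-block factor
#'
#' `1 / (1 + 0.28 * mg * exp(-0.062 * V))`: the fraction of the NMDA
#' conductance not blocked by magnesium at membrane potential `V` (mV).
#' Strictly increasing in `V`, bounded in (0, 1].
#'
#' @param V membrane potential (mV), vectorised.
#' @param mg magnesium concentration (mM).
#' @return dimensionless factor in (0, 1].
#' @export
nmda_block_factor <- function(V, mg = 1) {
  if (any(mg < 0)) stop("mg must be non-negative", call. = FALSE)
  1 / (1 + 0.28 * mg * exp(-0.062 * V))
}

#' Double-exponential synaptic conductance time course
#'
#' `g(t) = w * (exp(-t/tau_decay) - exp(-t/tau_rise)) / norm` for `t >= 0`
#' (0 before onset), normalised so the peak equals the weight.
#'
#' @param t_ms time since synaptic onset (ms), vectorised.
#' @param params a [synapse_params()].
#' @return conductance (uS).
#' @export
double_exp_conductance <- function(t_ms, params) {
  stopifnot(inherits(params, "synapse_params"))
  tr <- params$tau_rise_ms; td <- params$tau_decay_ms
  tp <- tr * td / (td - tr) * log(td / tr)
  nrm <- exp(-tp / td) - exp(-tp / tr)
  g <- ifelse(t_ms < 0, 0,
              params$weight_uS * (exp(-t_ms / td) - exp(-t_ms / tr)) / nrm)
  g
}

#' Time of the conductance peak of a double-exponential synapse (ms)
#' @param params a [synapse_params()].
#' @export
double_exp_peak_time <- function(params) {
  tr <- params$tau_rise_ms; td <- params$tau_decay_ms
  tr * td / (td - tr) * log(td / tr)
}
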