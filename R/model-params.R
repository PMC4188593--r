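# Model parameterization.  The cell is a single-compartment Hodgkin-Huxley
# type FSI with a transient Na+ current (instantaneous activation), a
# Kv3-like fast delayed rectifier (n^2) and a Kv1-like slowly inactivating
# D-current (fast activation a, slow inactivation b).  The D-current is the
# mechanistic knob of the package: it is partially open near rest (raising
# resting conductance and lowering input resistance) and brakes depolarization
# near rheobase (delaying the first spike).  All constants below are
# calibration, not measurements.

#' Gating-kinetics constants of the FSI model
#'
#' Returns the fixed constants of the model's gating functions.  Steady-state
#' curves are logistic, `1 / (1 + exp(-(V - theta) / sigma))`; time constants
#' are in ms.  These constants define the model and are not meant to be tuned
#' per cell; per-cell variability enters through the maximal conductances
#' (see [fsi_params()]).
#'
#' @return Named list of gating constants (mV, ms).
#' @export
fsi_kinetics <- function() {
  list(
    # Na+: m instantaneous, h inactivation
    th_m = -28,   sig_m = 9,
    th_h = -58.3, sig_h = -6.7,
    tauh0 = 0.5, tauh1 = 13.5, tauh_th = -60, tauh_sig = -12,
    # Kv3-like delayed rectifier (n^2)
    th_n = -12.4, sig_n = 6.8,
    taun0 = 0.087, taun1 = 11.4,
    taunA_th = -14.6, taunA_sig = -8.6,
    taunB_th = 1.3,   taunB_sig = 18.7,
    # Kv1-like D-current: low-threshold fast activation, slow inactivation
    th_a = -60, sig_a = 16, tau_a = 2,
    th_b = -70, sig_b = -6, tau_b = 100, b_min = 0.4,
    # slow spike-activated adaptation K+ gate
    th_z = -30, sig_z = 5, tau_z = 120
  )
}

#' @noRd
gating_inf <- function(V, theta, sigma) 1 / (1 + exp(-(V - theta) / sigma))

# Flatten parameters for the C++ integrator.
#' @noRd
pack_membrane <- function(p) {
  c(p$Cm, p$g_L, p$g_Na, p$g_Kv3, p$g_Kd, p$g_adapt, p$E_L, p$E_Na, p$E_K)
}

#' @noRd
pack_kinetics <- function(k) {
  as.numeric(unlist(k[c(
    "th_m", "sig_m", "th_h", "sig_h", "tauh0", "tauh1", "tauh_th", "tauh_sig",
    "th_n", "sig_n", "taun0", "taun1", "taunA_th", "taunA_sig",
    "taunB_th", "taunB_sig", "th_a", "sig_a", "tau_a", "th_b", "sig_b", "tau_b", "b_min",
    "th_z", "sig_z", "tau_z"
  )]))
}

# Steady-state whole-cell current (pA, outward positive) at clamped V with
# gates at their steady state; used to place the leak reversal.
#' @noRd
steady_current <- function(p, V) {
  .fsi_steady_current_cpp(pack_membrane(p), pack_kinetics(p$kinetics), V)
}

# Leak reversal that makes `v_rest` a fixed point of the full model.
#' @noRd
calibrate_E_L <- function(p, v_rest) {
  p$E_L <- v_rest
  i0 <- steady_current(p, v_rest)          # residual with E_L = v_rest
  v_rest + i0 / p$g_L                      # shift E_L to cancel it
}

#' Membrane parameters of a simulated FSI
#'
#' Builds the parameter set of one simulated cell.  The `"vehicle"` preset is
#' calibrated so that standard feature extraction on its sweeps yields values
#' in the range reported for healthy layer-IV FSIs (input resistance near
#' 100 MOhm, spike half-width near 0.4 ms, a first-spike latency floor of
#' tens of ms near rheobase).  The `"mk801"` preset models the
#' NMDA-hypofunction phenotype: the Kv1-like D-current conductance `g_Kd` is
#' reduced to 25%, which raises input resistance and abolishes the delayed
#' first spike; the Kv3 conductance is modestly reduced (immature, broader
#' spikes, more accommodation).  The leak reversal is recalibrated per preset
#' so both cells rest near their reported resting potentials.
#'
#' @param preset `"vehicle"`, `"mk801"`, or `"custom"`.
#' @param ... Named overrides of any field (e.g. `g_Kd = 0`).
#' @return Object of class `fsi_params`: capacitance `Cm` (pF), maximal
#'   conductances `g_L`, `g_Na`, `g_Kv3`, `g_Kd` (nS), reversals `E_L`,
#'   `E_Na`, `E_K` (mV), current-noise SD `noise_sigma` (pA), target resting
#'   potential `v_rest` (mV), `label`, and the `kinetics` constant list.
#' @export
fsi_params <- function(preset = c("vehicle", "mk801", "custom"), ...) {
  preset <- match.arg(preset)
  base <- list(
    Cm = 66, g_L = 5.2, g_Na = 7400, g_Kv3 = 14800, g_Kd = 22, g_adapt = 0,
    E_L = NA_real_, E_Na = 50, E_K = -90,
    noise_sigma = 2, v_rest = -65.5,
    label = preset, kinetics = fsi_kinetics()
  )
  if (preset == "mk801") {
    base$g_Kd <- base$g_Kd * 0.25
    base$g_Kv3 <- base$g_Kv3 * 0.60
    base$g_adapt <- 50
    base$v_rest <- -66.9
  }
  p <- modifyList(base, list(...))
  p$label <- p$label %||% preset
  class(p) <- "fsi_params"
  validate_fsi_params(p)
  if (is.na(p$E_L)) p$E_L <- calibrate_E_L(p, p$v_rest)
  p
}

#' @noRd
validate_fsi_params <- function(p) {
  gs <- c(p$g_L, p$g_Na, p$g_Kv3, p$g_Kd, p$g_adapt)
  if (any(!is.finite(gs)) || any(gs < 0))
    fsi_error("all conductances must be finite and >= 0", "invalid_params")
  if (!is_scalar_number(p$Cm) || p$Cm <= 0)
    fsi_error("Cm must be > 0", "invalid_params")
  if (!(p$E_Na > 0 && p$E_K < 0))
    fsi_error("reversal potentials must satisfy E_Na > 0 > E_K",
              "invalid_params")
  invisible(p)
}

#' Small-signal (slope) input resistance of the model at a voltage
#'
#' Numerical derivative of the steady-state current-voltage relation, with
#' gates at steady state.  Used to check that the `mk801` preset has a higher
#' derived input resistance than `vehicle`.
#'
#' @param params `fsi_params` object.
#' @param V Voltage at which to evaluate (mV); default the preset's resting
#'   potential.
#' @return Resistance in MOhm.
#' @export
slope_resistance <- function(params, V = params$v_rest) {
  dV <- 0.5
  g <- (steady_current(params, V + dV) - steady_current(params, V - dV)) /
    (2 * dV)                               # nS
  1000 / g                                 # MOhm
}

#' Synaptic parameters of a simulated FSI
#'
#' Peak conductances and kinetics for AMPA, GluN2A-like and GluN2B-like NMDA
#' components, spontaneous event rates, the minimal-stimulation failure
#' probability and the ifenprodil block fraction.  The NMDA conductance is
#' split by `frac_GluN2B`; the GluN2B-like component always decays more
#' slowly than the GluN2A-like one.  The `"mk801"` preset raises
#' `frac_GluN2B` to 0.9 and slows the GluN2B decay so the weighted decay
#' constant of the composite NMDA EPSC is near 170 ms (vehicle: near 54 ms).
#'
#' @param preset `"vehicle"`, `"mk801"`, or `"custom"`.
#' @param ... Named overrides.
#' @return Object of class `fsi_syn_params` (conductances nS, times ms,
#'   rates Hz, Mg in mM).
#' @export
synaptic_params <- function(preset = c("vehicle", "mk801", "custom"), ...) {
  preset <- match.arg(preset)
  base <- list(
    g_AMPA = 1.4, g_NMDA = 2.6, frac_GluN2B = 0.35,
    tau_rise_AMPA = 0.2,  tau_decay_AMPA = 3.0,
    tau_rise_NMDA_A = 3,  tau_decay_NMDA_A = 25,
    tau_rise_NMDA_B = 8,  tau_decay_NMDA_B = 108,
    Mg_mM = 2, E_exc = 10, E_inh = -40,
    p_failure = 0.5,
    rate_sEPSC = 22, rate_sIPSC = 8, frac_nmda_only = 0.25,
    g_spont_exc = 1.0, g_spont_inh = 1.5,
    tau_rise_inh = 0.5, tau_decay_inh = 8,
    amp_sdlog = 0.3,
    ifenprodil_block = 0,
    label = preset
  )
  if (preset == "mk801") {
    base$frac_GluN2B <- 0.9
    base$tau_decay_NMDA_B <- 185
    base$tau_decay_AMPA <- 4.8
    base$rate_sEPSC <- 32
    base$frac_nmda_only <- 0.35
  }
  s <- modifyList(base, list(...))
  s$label <- s$label %||% preset
  class(s) <- "fsi_syn_params"
  validate_syn_params(s)
  s
}

#' @noRd
validate_syn_params <- function(s) {
  if (s$frac_GluN2B < 0 || s$frac_GluN2B > 1)
    fsi_error("frac_GluN2B must be in [0, 1]", "invalid_params")
  if (s$p_failure < 0 || s$p_failure > 1)
    fsi_error("p_failure must be in [0, 1]", "invalid_params")
  if (s$ifenprodil_block < 0 || s$ifenprodil_block > 1)
    fsi_error("ifenprodil_block must be in [0, 1]", "invalid_params")
  if (s$tau_decay_NMDA_B <= s$tau_decay_NMDA_A)
    fsi_error("GluN2B decay constant must exceed GluN2A decay constant",
              "invalid_params")
  invisible(s)
}
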