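# Voltage-clamp simulation.  Under voltage clamp the membrane current is a
# sum of synaptic conductance transients times driving force, with the NMDA
# components additionally scaled by the voltage-dependent Mg2+ block factor.
# Conductance transients are difference-of-exponentials kernels rendered by
# two one-pole recursive filters over impulse trains, which is exact for the
# discretized kernel and O(n) in trace length.

#' Voltage-dependent Mg2+ block factor of the NMDA conductance
#'
#' Standard single-exponential voltage dependence,
#' `1 / (1 + (Mg / K_half) * exp(-V / V_slope))`.  Equals 1 with no Mg,
#' increases with depolarization, decreases with Mg concentration.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param Mg_mM External Mg2+ concentration (mM), >= 0.
#' @param K_half Half-blocking concentration at 0 mV (mM).
#' @param V_slope Voltage sensitivity (mV per e-fold).
#' @return Unblocked fraction in (0, 1\].
#' @export
mg_block_factor <- function(V, Mg_mM, K_half = 3.57, V_slope = 16.13) {
  if (any(Mg_mM < 0)) fsi_error("Mg_mM must be >= 0", "invalid_params")
  1 / (1 + (Mg_mM / K_half) * exp(-V / V_slope))
}

# Difference-of-exponentials kernel scale: value of
# exp(-t/tau_d) - exp(-t/tau_r) at its peak, so an impulse of weight
# g_peak / kernel_peak yields a transient with peak conductance g_peak.
#' @noRd
kernel_peak_factor <- function(tau_r, tau_d) {
  tp <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  exp(-tp / tau_d) - exp(-tp / tau_r)
}

# Render sum_i w_i * (exp(-(t - t_i)/tau_d) - exp(-(t - t_i)/tau_r)) on a
# uniform grid via two recursive one-pole filters.
#' @noRd
render_kernel_train <- function(n, dt, idx, w, tau_r, tau_d) {
  imp <- numeric(n)
  keep <- idx >= 1 & idx <= n
  if (any(keep)) {
    tab <- tapply(w[keep], idx[keep], sum)
    imp[as.integer(names(tab))] <- tab
  }
  yd <- stats::filter(imp, exp(-dt / tau_d), method = "recursive")
  yr <- stats::filter(imp, exp(-dt / tau_r), method = "recursive")
  as.numeric(yd - yr)
}

#' @noRd
draw_event_times <- function(rate_hz, duration_ms) {
  n <- rpois(1, rate_hz * duration_ms / 1000)
  sort(runif(n, 0, duration_ms))
}

#' Simulate a voltage-clamp sweep
#'
#' Generates membrane current at a fixed holding potential: spontaneous
#' excitatory events (a fraction of which are NMDA-only), spontaneous
#' inhibitory events, and optionally evoked EPSCs under a minimal-stimulation
#' protocol in which each pulse fails independently with probability
#' `p_failure`.  Event times, classes and amplitudes are drawn before any
#' rendering, so traces that differ only in Mg2+ or ifenprodil share
#' identical event sequences at the same seed.
#'
#' @param params `fsi_params` (supplies the recording-noise SD).
#' @param syn `fsi_syn_params`.
#' @param protocol `fsi_protocol` with `mode = "voltage_clamp"`.
#' @param seed Integer seed.
#' @param cell_id,group_label Metadata.
#' @param tags Character vector of condition tags stored on the sweep (e.g.
#'   `c("glycine", "DNQX", "SR95531")`).
#' @param label Condition label (`"AMPA"`, `"NMDA"`, `""`).
#' @return An `fsi_sweep_set` with one sweep; signal is current (pA),
#'   stimulus marks evoked pulses.  The sweep's `meta$failures` records the
#'   per-pulse failure draws.
#' @export
simulate_voltage_clamp <- function(params, syn, protocol, seed = 1L,
                                   cell_id = syn$label,
                                   group_label = syn$label,
                                   tags = character(0), label = "") {
  if (!identical(protocol$mode, "voltage_clamp"))
    fsi_error("protocol mode must be voltage-clamp", "wrong_mode")
  if (protocol$holding < -100 || protocol$holding > 80)
    fsi_error("holding potential outside [-100, +80] mV", "out_of_range")
  set.seed(seed)
  khz <- protocol$sampling_khz
  dt <- 1 / khz
  n <- round(protocol$duration * khz)
  V <- protocol$holding
  mg <- mg_block_factor(V, syn$Mg_mM)
  df_exc <- V - syn$E_exc
  df_inh <- V - syn$E_inh

  # --- draw all randomness first (fixed order) ---
  t_exc <- draw_event_times(syn$rate_sEPSC, protocol$duration)
  cls_nmda_only <- runif(length(t_exc)) < syn$frac_nmda_only
  w_exc <- rlnorm(length(t_exc), 0, syn$amp_sdlog)
  t_inh <- draw_event_times(syn$rate_sIPSC, protocol$duration)
  w_inh <- rlnorm(length(t_inh), 0, syn$amp_sdlog)
  n_pulse <- length(protocol$pulse_times)
  failures <- if (n_pulse) runif(n_pulse) < syn$p_failure else logical(0)
  w_ev <- rlnorm(n_pulse, 0, 0.1)

  g_exc_total <- numeric(n)
  current <- numeric(n)

  add_component <- function(idx, w, g_peak, tau_r, tau_d) {
    if (g_peak <= 0 || !length(idx)) return(numeric(n))
    render_kernel_train(n, dt, idx, w * g_peak / kernel_peak_factor(tau_r, tau_d),
                        tau_r, tau_d)
  }

  idx_exc <- round(t_exc * khz) + 1L
  idx_inh <- round(t_inh * khz) + 1L
  idx_ev <- round(protocol$pulse_times * khz) + 1L
  idx_ev_s <- idx_ev[!failures]
  w_ev_s <- w_ev[!failures]

  gB_eff <- syn$g_NMDA * syn$frac_GluN2B * (1 - syn$ifenprodil_block)
  gA_eff <- syn$g_NMDA * (1 - syn$frac_GluN2B)

  # spontaneous AMPA (events that are not NMDA-only)
  g_ampa <- add_component(idx_exc[!cls_nmda_only], w_exc[!cls_nmda_only],
                          syn$g_spont_exc, syn$tau_rise_AMPA,
                          syn$tau_decay_AMPA)
  # spontaneous NMDA (all excitatory events), split GluN2A / GluN2B
  sc_n <- syn$g_spont_exc / max(syn$g_AMPA, 1e-12)  # spont/evoked scale
  g_nmda <- add_component(idx_exc, w_exc, gA_eff * sc_n,
                          syn$tau_rise_NMDA_A, syn$tau_decay_NMDA_A) +
            add_component(idx_exc, w_exc, gB_eff * sc_n,
                          syn$tau_rise_NMDA_B, syn$tau_decay_NMDA_B)
  # evoked components
  g_ampa <- g_ampa + add_component(idx_ev_s, w_ev_s, syn$g_AMPA,
                                   syn$tau_rise_AMPA, syn$tau_decay_AMPA)
  g_nmda <- g_nmda + add_component(idx_ev_s, w_ev_s, gA_eff,
                                   syn$tau_rise_NMDA_A, syn$tau_decay_NMDA_A) +
                    add_component(idx_ev_s, w_ev_s, gB_eff,
                                  syn$tau_rise_NMDA_B, syn$tau_decay_NMDA_B)
  g_inh <- add_component(idx_inh, w_inh, syn$g_spont_inh,
                         syn$tau_rise_inh, syn$tau_decay_inh)

  current <- (g_ampa + g_nmda * mg) * df_exc + g_inh * df_inh
  if (params$noise_sigma > 0)
    current <- current + rnorm(n, 0, params$noise_sigma)

  stim <- numeric(n)
  if (n_pulse) {
    wi <- max(1L, round(protocol$pulse_width * khz))
    for (k in seq_len(n_pulse))
      stim[idx_ev[k]:min(n, idx_ev[k] + wi - 1L)] <- protocol$pulse_amplitude
  }

  sw <- new_sweep(current, stim, khz, "voltage_clamp", cell_id = cell_id,
                  group_label = group_label,
                  meta = list(holding = V, pulse_times = protocol$pulse_times,
                              failures = failures),
                  conditions = list(Mg_mM = syn$Mg_mM,
                                    drug = if (syn$ifenprodil_block > 0)
                                      "ifenprodil" else "none",
                                    tags = tags, label = label))
  new_sweep_set(list(sw), protocol, cell_id, group_label)
}

#' Pharmacological NMDA isolation (DNQX + gabazine + glycine)
#'
#' Returns synaptic parameters with AMPA and inhibitory conductances and all
#' spontaneous activity removed, and the condition tags the isolation
#' cocktail implies.
#'
#' @param syn `fsi_syn_params`.
#' @return List with elements `syn` and `tags`.
#' @export
isolate_nmda <- function(syn) {
  syn$g_AMPA <- 0
  syn$g_spont_exc <- 0
  syn$g_spont_inh <- 0
  syn$rate_sEPSC <- 0
  syn$rate_sIPSC <- 0
  list(syn = syn, tags = c("glycine", "DNQX", "SR95531"))
}
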