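# Stimulus protocols.  Times in ms, currents in pA, holding potentials in mV.

#' Current-step protocol
#'
#' A family of square current steps delivered from rest, one sweep per
#' amplitude.  Step duration defaults to 600 ms, the standard used for both
#' the hyperpolarizing (passive) and depolarizing (spiking) series.
#'
#' @param amplitudes Ordered numeric vector of step amplitudes (pA).
#' @param onset Step onset within the sweep (ms).
#' @param duration Step duration (ms).
#' @param sweep_duration Total sweep length (ms).
#' @param sampling_khz Sampling rate of emitted sweeps (kHz).
#' @param increment Amplitude increment per sweep (pA) when the protocol is
#'   used for a rheobase search; must lie in \[1, 5\].
#' @param inter_sweep_interval Seconds between sweeps (metadata only).
#' @return Object of class `fsi_protocol` with `mode = "current_clamp"`.
#' @export
step_protocol <- function(amplitudes, onset = 100, duration = 600,
                          sweep_duration = onset + duration + 300,
                          sampling_khz = 20, increment = NULL,
                          inter_sweep_interval = 5) {
  if (duration <= 0) fsi_error("step duration must be > 0", "invalid_protocol")
  if (!is.null(increment) && (increment < 1 || increment > 5))
    fsi_error("rheobase increment must be within [1, 5] pA",
              "invalid_protocol")
  structure(
    list(mode = "current_clamp", amplitudes = as.numeric(amplitudes),
         step_onset = onset, step_duration = duration,
         sweep_duration = sweep_duration, sampling_khz = sampling_khz,
         increment = increment, inter_sweep_interval = inter_sweep_interval),
    class = "fsi_protocol")
}

#' Voltage-clamp protocol
#'
#' A voltage-clamp epoch at a fixed holding potential, optionally with
#' evoked stimulation pulses (0.2 ms pulses delivered once per period).
#'
#' @param holding Holding potential (mV); must lie in \[-100, 80\].
#' @param duration Sweep length (ms).
#' @param sampling_khz Sampling rate (kHz).
#' @param n_pulses Number of evoked pulses (0 for spontaneous recording).
#' @param pulse_period Inter-pulse interval (ms); the standard evoked
#'   protocol delivers one pulse every 15 s.
#' @param first_pulse Time of the first pulse (ms).
#' @param pulse_amplitude Stimulator intensity (arbitrary units, metadata).
#' @param pulse_width Pulse width (ms).
#' @return Object of class `fsi_protocol` with `mode = "voltage_clamp"`.
#' @export
vc_protocol <- function(holding, duration = 10000, sampling_khz = 20,
                        n_pulses = 0, pulse_period = 15000,
                        first_pulse = 100, pulse_amplitude = 30,
                        pulse_width = 0.2) {
  if (holding < -100 || holding > 80)
    fsi_error(sprintf("holding potential %g mV outside [-100, +80] mV",
                      holding), "out_of_range")
  pulse_times <- if (n_pulses > 0)
    first_pulse + pulse_period * (seq_len(n_pulses) - 1) else numeric(0)
  structure(
    list(mode = "voltage_clamp", holding = holding, duration = duration,
         sampling_khz = sampling_khz, pulse_times = pulse_times,
         pulse_amplitude = pulse_amplitude, pulse_width = pulse_width,
         pulse_period = pulse_period),
    class = "fsi_protocol")
}
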