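# Rheobase, first-spike latency, latency-current regimes, threshold dynamics
# and spike-train features.

#' Find the rheobase current
#'
#' Scans amplitudes upward until one is found whose three consecutive trials
#' each contain exactly one spike (the rheobase rule).  Cells that begin
#' firing with two or more spikes on every trial without ever meeting the
#' single-spike criterion are reported as excluded; scans that exhaust the
#' range without any spike raise a not-found signal carrying the scan record.
#'
#' @param provider Function `(amplitude_pA, trial)` returning a current-clamp
#'   `fsi_sweep`.  For simulated cells see [make_cell_provider()].
#' @param start_pA First amplitude tested (pA).
#' @param increment Amplitude increment per sweep (pA), in \[1, 5\].
#' @param max_pA Largest amplitude tested before giving up.
#' @param n_trials Consecutive trials required (default 3).
#' @param dvdt_threshold Spike criterion passed to [detect_spikes()].
#' @param criterion `"single_spike"` (the strict rheobase rule: exactly one
#'   spike on all trials) or `"any_spike"` (smallest amplitude with at least
#'   one spike on all trials; used for cells, e.g. Kv1-null models, that jump
#'   straight from silence to repetitive firing and can never satisfy the
#'   strict rule).
#' @return List of class `fsi_rheobase`: `I_th` (pA), `latency_sweep` (the
#'   first trial sweep at `I_th`), and the `scan` record (amplitude x trial
#'   spike counts).
#' @export
find_rheobase <- function(provider, start_pA = 50, increment = 5,
                          max_pA = 600, n_trials = 3, dvdt_threshold = 10,
                          criterion = c("single_spike", "any_spike")) {
  criterion <- match.arg(criterion)
  if (increment < 1 || increment > 5)
    fsi_error("increment must be within [1, 5] pA", "invalid_protocol")
  scan <- list()
  amp <- start_pA
  consec_multi <- 0L
  while (amp <= max_pA) {
    counts <- integer(n_trials)
    sweeps <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      sweeps[[tr]] <- provider(amp, tr)
      counts[tr] <- nrow(detect_spikes(sweeps[[tr]],
                                       dvdt_threshold = dvdt_threshold))
    }
    scan[[length(scan) + 1L]] <- data.frame(amplitude = amp,
                                            trial = seq_len(n_trials),
                                            n_spikes = counts)
    hit <- if (criterion == "single_spike") all(counts == 1L) else
      all(counts >= 1L)
    if (hit) {
      out <- list(I_th = amp, latency_sweep = sweeps[[1]],
                  scan = do.call(rbind, scan))
      class(out) <- "fsi_rheobase"
      return(out)
    }
    if (criterion == "single_spike" && all(counts >= 2L))
      consec_multi <- consec_multi + 1L else consec_multi <- 0L
    if (consec_multi >= 3L)
      fsi_error(sprintf(
        "cell never met the single-spike rheobase criterion (firing >= 2 spikes from %g pA)",
        amp - (consec_multi - 1) * increment),
        "excluded_cell", data = list(scan = do.call(rbind, scan)))
    amp <- amp + increment
  }
  fsi_error("amplitude scan exhausted without meeting the rheobase criterion",
            "rheobase_not_found", data = list(scan = do.call(rbind, scan)))
}

#' Sweep provider for a simulated cell
#'
#' Returns a function `(amplitude, trial)` -> `fsi_sweep` that simulates one
#' 600 ms step, with reproducible per-(amplitude, trial) noise derived from
#' the base seed.
#'
#' @param params `fsi_params`.
#' @param seed Base seed.
#' @param onset,duration Step timing (ms).
#' @param sampling_khz Sampling rate (kHz).
#' @return Provider function.
#' @export
make_cell_provider <- function(params, seed = 1L, onset = 100,
                               duration = 600, sampling_khz = 20) {
  force(params)
  function(amplitude, trial) {
    sub_seed <- (abs(seed) + round(997 * amplitude) + 131071 * trial) %%
      2147483647L
    prot <- step_protocol(amplitude, onset = onset, duration = duration,
                          sampling_khz = sampling_khz)
    simulate_current_clamp(params, prot, seed = sub_seed)[[1]]
  }
}

#' First-spike latency of a sweep
#'
#' Time from stimulus onset to the threshold crossing of the first spike.
#'
#' @param sweep Current-clamp `fsi_sweep` with `meta$step_onset`.
#' @param dvdt_threshold Spike criterion (mV/ms).
#' @return Latency in ms.
#' @export
first_spike_latency <- function(sweep, dvdt_threshold = 10) {
  sp <- detect_spikes(sweep, dvdt_threshold = dvdt_threshold)
  if (nrow(sp) == 0)
    fsi_error("sweep contains no spike; latency undefined", "no_spike")
  onset <- sweep$meta$step_onset
  if (is.null(onset))
    fsi_error("stimulus onset unknown; cannot compute latency", "no_spike")
  sp$threshold_t[1] - onset
}

#' Latency-current curve and regime classification
#'
#' Computes per-sweep (log10 current, log10 latency) pairs, fits a line to
#' the low-intensity regime (amplitude < 2 x I_th), and summarizes the
#' high-intensity regime (> 2 x I_th) by its latency coefficient of
#' variation and slope.  A stimulus-insensitive latency floor is declared
#' when the high-regime CV is below `floor_cv` and the high-regime slope
#' magnitude is less than half the low-regime slope magnitude.
#'
#' @param sweep_set Current-clamp `fsi_sweep_set` of suprathreshold steps.
#' @param I_th Rheobase (pA).
#' @param floor_cv CV bound for the floor call.
#' @param dvdt_threshold Spike criterion (mV/ms).
#' @return List of class `fsi_latency_curve`: `points` (amplitude, latency,
#'   regime), `low_slope`, `high_slope`, `high_cv`, `low_evaluable`,
#'   `high_evaluable`, `floor_present`.
#' @export
latency_current_curve <- function(sweep_set, I_th, floor_cv = 0.20,
                                  dvdt_threshold = 10) {
  pts <- do.call(rbind, lapply(sweep_set$sweeps, function(s) {
    lat <- tryCatch(first_spike_latency(s, dvdt_threshold),
                    fsiephys_no_spike = function(e) NA_real_)
    data.frame(amplitude = s$meta$amplitude, latency = lat)
  }))
  pts <- pts[is.finite(pts$latency) & pts$latency > 0, , drop = FALSE]
  pts$regime <- ifelse(pts$amplitude < 2 * I_th, "low", "high")
  lo <- pts[pts$regime == "low", ]
  hi <- pts[pts$regime == "high", ]
  low_ok <- nrow(lo) >= 3
  high_ok <- nrow(hi) >= 3
  low_slope <- if (low_ok)
    coef(lm(log10(latency) ~ log10(amplitude), data = lo))[[2]] else NA_real_
  high_slope <- if (high_ok)
    coef(lm(log10(latency) ~ log10(amplitude), data = hi))[[2]] else NA_real_
  high_cv <- if (high_ok) {
    if (mean(hi$latency) == 0) 0 else sd(hi$latency) / mean(hi$latency)
  } else NA_real_
  floor_present <- if (low_ok && high_ok) {
    isTRUE(high_cv < floor_cv) &&
      (abs(high_slope) < abs(low_slope) / 2 ||
         (low_slope == 0 && high_slope == 0))
  } else NA
  out <- list(points = pts, low_slope = low_slope, high_slope = high_slope,
              high_cv = high_cv, low_evaluable = low_ok,
              high_evaluable = high_ok, floor_present = floor_present)
  class(out) <- "fsi_latency_curve"
  out
}

#' Spike-threshold dynamics
#'
#' Ordinary least-squares slope of the first-spike threshold voltage on
#' injected current amplitude, over a sweep family at rheobase and
#' incremented amplitudes.  Sweeps lacking a spike are omitted and counted.
#'
#' @param sweep_set Current-clamp `fsi_sweep_set`.
#' @param dvdt_threshold Spike criterion (mV/ms).
#' @return List: `slope` (mV/pA), `points`, `n_omitted`.
#' @export
threshold_dynamics <- function(sweep_set, dvdt_threshold = 10) {
  pts <- do.call(rbind, lapply(sweep_set$sweeps, function(s) {
    sp <- detect_spikes(s, dvdt_threshold = dvdt_threshold)
    data.frame(amplitude = s$meta$amplitude,
               threshold_V = if (nrow(sp)) sp$threshold_V[1] else NA_real_)
  }))
  omitted <- sum(!is.finite(pts$threshold_V))
  use <- pts[is.finite(pts$threshold_V), , drop = FALSE]
  slope <- if (nrow(use) >= 2) {
    if (var(use$threshold_V) == 0) 0 else
      coef(lm(threshold_V ~ amplitude, data = use))[[2]]
  } else NA_real_
  list(slope = slope, points = pts, n_omitted = omitted)
}

#' Spike-train features at a saturating amplitude
#'
#' Maximum spike frequency (spike count / step duration), the ISI
#' accommodation ratio (first interspike interval / mean of the last three),
#' and the amplitude ratio of the first to the second spike
#' (threshold-to-peak amplitudes).  Features needing five spikes are `NA`
#' (with `reason`) on shorter trains.
#'
#' @param sweep Current-clamp `fsi_sweep` at the largest tested amplitude.
#' @param dvdt_threshold Spike criterion (mV/ms).
#' @return List: `max_spike_freq` (Hz), `max_inst_freq` (Hz, 1/min ISI),
#'   `accommodation_ratio_ISI`, `amp_ratio_1st_2nd`, `n_spikes`, `reason`.
#' @export
train_features <- function(sweep, dvdt_threshold = 10) {
  sp <- detect_spikes(sweep, dvdt_threshold = dvdt_threshold)
  dur_s <- sweep$meta$step_duration / 1000
  n <- nrow(sp)
  out <- list(max_spike_freq = n / dur_s, max_inst_freq = NA_real_,
              accommodation_ratio_ISI = NA_real_,
              amp_ratio_1st_2nd = NA_real_, n_spikes = n, reason = NULL)
  if (n < 5) {
    out$reason <- "fewer than 5 spikes; train ratios not evaluable"
    if (n >= 2) {
      isi <- diff(sp$threshold_t)
      out$max_inst_freq <- 1000 / min(isi)
      amps <- sp$peak_V - sp$threshold_V
      out$amp_ratio_1st_2nd <- amps[1] / amps[2]
    }
    return(out)
  }
  isi <- diff(sp$threshold_t)
  out$max_inst_freq <- 1000 / min(isi)
  out$accommodation_ratio_ISI <- isi[1] / mean(tail(isi, 3))
  amps <- sp$peak_V - sp$threshold_V
  out$amp_ratio_1st_2nd <- amps[1] / amps[2]
  out
}
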