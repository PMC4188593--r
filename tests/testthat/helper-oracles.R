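# Naive, sample-by-sample reference implementations used as independent
# oracles for the vectorized feature extraction, plus synthetic-trace
# builders.

# Brute-force spike scan: explicit loops over samples, applying the same
# definitions (central-difference dV/dt, threshold at the first sample
# reaching the criterion, peak within 5 ms, minimum amplitude, repolarization
# between spikes, interpolated half-width).
oracle_spikes <- function(v, dt, thr = 10, min_amp = 20) {
  n <- length(v)
  d <- rep(NA_real_, n)
  for (i in 2:(n - 1)) d[i] <- (v[i + 1] - v[i - 1]) / (2 * dt)
  win <- round(5 / dt)
  res <- list()
  prev_peak <- NA
  for (i in 2:(n - 1)) {
    if (is.na(d[i]) || d[i] < thr) next
    if (!is.na(d[i - 1]) && d[i - 1] >= thr) next    # not a rising edge
    peak <- i
    for (k in i:min(n, i + win)) if (v[k] > v[peak]) peak <- k
    if (!is.na(prev_peak) && peak == prev_peak) next  # same upstroke
    if (v[peak] - v[i] < min_amp) next
    if (!is.na(prev_peak)) {
      m <- Inf
      for (k in prev_peak:i) m <- min(m, v[k])
      if (m >= v[i]) next                              # no repolarization
    }
    half <- (v[i] + v[peak]) / 2
    t_up <- NA_real_
    for (j in (i + 1):peak) {
      if (j > n || is.na(v[j])) break
      if (v[j] >= half) {
        t_up <- (j - 2 + (half - v[j - 1]) / (v[j] - v[j - 1])) * dt
        break
      }
    }
    t_dn <- NA_real_
    for (j in (peak + 1):min(n, peak + round(10 / dt))) {
      if (j > n || is.na(v[j])) break
      if (v[j] <= half) {
        t_dn <- (j - 2 + (v[j - 1] - half) / (v[j - 1] - v[j])) * dt
        break
      }
    }
    res[[length(res) + 1]] <- data.frame(
      threshold_t = (i - 1) * dt, threshold_V = v[i],
      peak_t = (peak - 1) * dt, peak_V = v[peak],
      half_width = t_dn - t_up)
    prev_peak <- peak
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(threshold_t = numeric(0), threshold_V = numeric(0),
               peak_t = numeric(0), peak_V = numeric(0),
               half_width = numeric(0))
}

# OLS slope by explicit normal equations.
oracle_ols_slope <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  sum((x - xb) * (y - yb)) / sum((x - xb)^2)
}

# Stereotyped spike waveform (about 3 ms long, ~45 mV amplitude) that starts
# slowly, crosses the 10 mV/ms criterion mid-upstroke, peaks, repolarizes
# below baseline and recovers.
spike_template <- function(khz = 20, amp = 45) {
  t_up <- seq(0, 1.2, by = 1 / khz)             # slow-to-fast upstroke
  up <- amp * (t_up / 1.2)^3
  t_dn <- seq(1 / khz, 1.5, by = 1 / khz)       # repolarization to -12
  dn <- amp - (amp + 12) * (t_dn / 1.5)
  t_rec <- seq(1 / khz, 4, by = 1 / khz)        # AHP recovery
  rec <- -12 * (1 - t_rec / 4)
  c(up, dn, rec)
}

# Current-clamp sweep with spikes inserted at given times (ms after sweep
# start), on a flat baseline.
synthetic_spike_sweep <- function(spike_times, baseline = -65, khz = 20,
                                  duration = 1000, onset = 100,
                                  step_duration = 600, amplitude = 100,
                                  spike_amp = 45) {
  n <- round(duration * khz)
  v <- rep(baseline, n)
  tpl <- spike_template(khz, spike_amp)
  for (ts in spike_times) {
    i0 <- round(ts * khz) + 1L
    idx <- i0:min(n, i0 + length(tpl) - 1L)
    v[idx] <- baseline + tpl[seq_along(idx)]
  }
  stim <- numeric(n)
  stim[(round(onset * khz) + 1):round((onset + step_duration) * khz)] <-
    amplitude
  new_sweep(v, stim, khz, "current_clamp",
            meta = list(step_onset = onset, step_duration = step_duration,
                        amplitude = amplitude))
}

# Voltage-clamp sweep with template EPSC events planted at given times.
synthetic_event_sweep <- function(event_times, amp = -50, khz = 20,
                                  duration_ms = 5000, tau_r = 0.5,
                                  tau_d = 4, noise = 0) {
  n <- round(duration_ms * khz)
  x <- numeric(n)
  tk <- seq(0, 30, by = 1 / khz)
  ker <- exp(-tk / tau_d) - exp(-tk / tau_r)
  ker <- ker / max(ker)
  for (ts in event_times) {
    i0 <- round(ts * khz) + 1L
    idx <- i0:min(n, i0 + length(ker) - 1L)
    x[idx] <- x[idx] + amp * ker[seq_along(idx)]
  }
  if (noise > 0) x <- x + rnorm(n, 0, noise)
  new_sweep(x, numeric(n), khz, "voltage_clamp", meta = list(holding = -40))
}

# Parameters of an ideal passive RC cell within the FSI model (all active
# conductances zero), with resistance R (MOhm) and time constant tau (ms).
rc_params <- function(R = 103, tau = 6.8, v_rest = -65) {
  gl <- 1000 / R
  fsi_params("custom", g_Na = 0, g_Kv3 = 0, g_Kd = 0, g_adapt = 0,
             g_L = gl, Cm = tau * gl, v_rest = v_rest, noise_sigma = 0,
             label = "rc")
}
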