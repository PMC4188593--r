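# Spike detection and phase plots.  Threshold is the first sample at which
# dV/dt reaches the criterion (default 10 mV/ms); dV/dt is computed by
# central differences on the raw, unsmoothed trace.

#' Phase plot (dV/dt versus Vm)
#'
#' @param sweep A current-clamp `fsi_sweep` (any trace is accepted; the
#'   derivative is taken on the raw samples).
#' @return Object of class `fsi_phase_plot`: data frame with columns `t`
#'   (ms), `Vm` (mV) and `dVdt` (mV/ms); endpoints are dropped by the central
#'   difference.
#' @export
phase_plot <- function(sweep) {
  v <- sweep$signal
  dt <- 1 / sweep$sampling_khz
  n <- length(v)
  i <- 2:(n - 1)
  out <- data.frame(t = (i - 1) * dt, Vm = v[i],
                    dVdt = (v[i + 1] - v[i - 1]) / (2 * dt))
  class(out) <- c("fsi_phase_plot", "data.frame")
  out
}

#' @noRd
central_dvdt <- function(v, dt) {
  n <- length(v)
  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d
}

#' Detect spikes and measure per-spike features
#'
#' A spike begins at the first sample where dV/dt >= `dvdt_threshold`
#' (threshold crossing).  Each crossing is validated against the baseline
#' rule: dV/dt at the crossing must exceed the mean absolute dV/dt over the
#' preceding baseline window by at least `baseline_fold`; crossings failing
#' validation are flagged in the `valid` column, not dropped.
#'
#' @param sweep Current-clamp `fsi_sweep` with >= 2 ms of pre-stimulus
#'   baseline.
#' @param dvdt_threshold Threshold-crossing criterion (mV/ms).
#' @param baseline_window Length of the pre-event baseline window (ms);
#'   must lie in \[10, 100\].
#' @param baseline_fold Required fold-change of dV/dt over baseline.
#' @param min_spike_amp Minimum threshold-to-peak amplitude (mV) for a
#'   crossing to count as a spike; rejects slow criterion crossings that are
#'   not followed by a regenerative upstroke.
#' @return Data frame of class `fsi_spike_features`, one row per spike:
#'   `threshold_t`, `threshold_V`, `peak_t`, `peak_V`, `half_width`,
#'   `AHP_amplitude` (positive, threshold minus trough), `t_AHP_peak` (peak
#'   to trough), `valid`.
#' @export
detect_spikes <- function(sweep, dvdt_threshold = 10, baseline_window = 50,
                          baseline_fold = 20, min_spike_amp = 20) {
  assert_mode(sweep, "current_clamp")
  if (baseline_window < 10 || baseline_window > 100)
    fsi_error("baseline_window must be within [10, 100] ms", "invalid_params")
  v <- sweep$signal
  dt <- 1 / sweep$sampling_khz
  n <- length(v)
  d <- central_dvdt(v, dt)
  supra <- !is.na(d) & d >= dvdt_threshold
  # rising edges of the supra-threshold mask
  edge <- which(supra & !c(FALSE, supra[-n]))
  empty <- data.frame(threshold_t = numeric(0), threshold_V = numeric(0),
                      peak_t = numeric(0), peak_V = numeric(0),
                      half_width = numeric(0), AHP_amplitude = numeric(0),
                      t_AHP_peak = numeric(0), valid = logical(0))
  class(empty) <- c("fsi_spike_features", "data.frame")
  if (!length(edge)) return(empty)

  # one spike per upstroke: keep edges whose following voltage peak is new
  win <- round(5 / dt)                      # peak search window, 5 ms
  peaks <- vapply(edge, function(i) {
    j <- i:min(n, i + win)
    j[which.max(v[j])]
  }, numeric(1))
  keep <- !duplicated(peaks) & (v[peaks] - v[edge]) >= min_spike_amp
  edge <- edge[keep]; peaks <- peaks[keep]
  if (!length(edge)) return(empty)
  # drop re-crossings during the repolarization/AHP of the same spike:
  # require the trace to fall below its threshold voltage between spikes
  if (length(edge) > 1) {
    ok <- rep(TRUE, length(edge))
    for (k in 2:length(edge)) {
      seg <- v[peaks[k - 1]:edge[k]]
      ok[k] <- min(seg) < v[edge[k]]
    }
    edge <- edge[ok]; peaks <- peaks[ok]
  }

  bw <- round(baseline_window / dt)
  rows <- lapply(seq_along(edge), function(k) {
    i <- edge[k]; p <- peaks[k]
    thr_v <- v[i]; thr_t <- (i - 1) * dt
    peak_v <- v[p]; peak_t <- (p - 1) * dt
    half <- (thr_v + peak_v) / 2
    # rising half crossing (interpolated)
    ri <- i + which(v[(i + 1):p] >= half)[1] - 0L
    t_up <- if (is.na(ri) || ri <= 1) NA_real_ else {
      j <- ri
      (j - 2 + (half - v[j - 1]) / (v[j] - v[j - 1])) * dt
    }
    # falling half crossing
    end_seg <- min(n, p + round(10 / dt))
    fi <- p + which(v[(p + 1):end_seg] <= half)[1]
    t_dn <- if (is.na(fi)) NA_real_ else {
      j <- fi
      (j - 2 + (v[j - 1] - half) / (v[j - 1] - v[j])) * dt
    }
    hw <- t_dn - t_up
    # AHP: trough between this peak and the next threshold crossing
    stop_i <- if (k < length(edge)) edge[k + 1] else min(n, p + round(30 / dt))
    seg <- v[p:stop_i]
    tr_rel <- which.min(seg)
    trough_v <- seg[tr_rel]
    ahp <- thr_v - trough_v
    t_ahp <- (p + tr_rel - 1 - p) * dt
    # baseline validation
    b0 <- max(1, i - bw); b1 <- max(1, i - round(1 / dt))
    base <- mean(abs(d[b0:b1]), na.rm = TRUE)
    valid <- is.finite(base) && d[i] >= baseline_fold * base
    data.frame(threshold_t = thr_t, threshold_V = thr_v, peak_t = peak_t,
               peak_V = peak_v, half_width = hw,
               AHP_amplitude = max(ahp, 0), t_AHP_peak = t_ahp,
               valid = valid)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fsi_spike_features", "data.frame")
  out
}

#' Read spike threshold graphically from a phase plot
#'
#' The membrane potential at which the phase trajectory first reaches the
#' dV/dt criterion.
#'
#' @param pp An `fsi_phase_plot`.
#' @param dvdt_threshold Criterion (mV/ms).
#' @return Threshold voltage (mV), or `NA` if never reached.
#' @export
phase_threshold <- function(pp, dvdt_threshold = 10) {
  i <- which(pp$dVdt >= dvdt_threshold)[1]
  if (is.na(i)) NA_real_ else pp$Vm[i]
}
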