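# Spontaneous synaptic event detection: derivative trigger followed by an
# amplitude criterion, with a refractory period.

#' Detect spontaneous synaptic events
#'
#' The lightly smoothed derivative of the trace is thresholded (trigger);
#' each trigger opens a peak-search window, and the event is accepted when
#' its baseline-to-peak amplitude exceeds the amplitude criterion (default
#' 3 x the baseline noise SD).  A refractory period suppresses re-triggering
#' on the same rising phase.  All detector parameters are returned with the
#' result.
#'
#' @param sweep Voltage-clamp `fsi_sweep`, at least 10 s long (shorter sweeps
#'   are accepted with `enforce_min = FALSE`, used by the planted-event
#'   tests).
#' @param polarity `"negative"` (inward) or `"positive"` (outward) events.
#' @param amp_threshold Amplitude criterion (pA); default `3 x` the estimated
#'   baseline noise SD.
#' @param deriv_k Trigger criterion in robust SDs of the smoothed derivative.
#' @param refractory_ms Refractory period (ms).
#' @param smooth_ms Boxcar width for the derivative trace (ms).
#' @param enforce_min Require >= 10 s of recording.
#' @return List of class `fsi_events`: `events` (data frame: `onset_t`,
#'   `peak_t`, `peak_amplitude` (pA, positive), `rise_10_90` (ms)),
#'   `frequency` (Hz), `duration_s`, `settings`.
#' @export
detect_events <- function(sweep, polarity = c("negative", "positive"),
                          amp_threshold = NULL, deriv_k = 3,
                          refractory_ms = 2, smooth_ms = 1,
                          enforce_min = TRUE) {
  assert_mode(sweep, "voltage_clamp")
  polarity <- match.arg(polarity)
  khz <- sweep$sampling_khz
  dur_s <- length(sweep$signal) / khz / 1000
  if (enforce_min && dur_s < 10)
    fsi_error("spontaneous-event detection needs >= 10 s of recording",
              "insufficient_protocol")
  x <- if (polarity == "negative") -sweep$signal else sweep$signal
  n <- length(x)
  dt <- 1 / khz

  w <- max(1L, round(smooth_ms * khz))
  xs <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  d <- c(0, diff(xs)) / dt
  sd_d <- stats::mad(d, na.rm = TRUE)
  noise_sd <- noise_sd_diff(x)
  if (is.null(amp_threshold)) amp_threshold <- 3 * noise_sd

  trig <- d > deriv_k * sd_d
  # hysteresis: bridge sub-ms dips in the trigger mask so one slow rise is
  # one event, not several
  r <- rle(trig)
  gap <- round(0.8 * khz)
  short_gap <- !r$values & r$lengths < gap
  if (length(r$values) > 2)
    short_gap[c(1, length(short_gap))] <- FALSE
  r$values[short_gap] <- TRUE
  trig <- inverse.rle(r)
  starts <- which(trig & !c(FALSE, trig[-n]))
  refr <- round(refractory_ms * khz)
  keep <- logical(length(starts))
  last <- -Inf
  for (i in seq_along(starts)) {
    if (starts[i] - last >= refr) { keep[i] <- TRUE; last <- starts[i] }
  }
  starts <- starts[keep]

  peak_win <- round(10 * khz)
  rows <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]
    # peak search capped at the next trigger so overlapping events are not
    # merged into one
    lim <- min(n, i + peak_win,
               if (k < length(starts)) starts[k + 1] - 1L else n)
    seg <- xs[i:lim]
    p_rel <- which.max(seg)
    base <- min(xs[max(1, i - round(0.5 * khz)):i])  # local pre-trigger level
    amp <- seg[p_rel] - base
    if (amp < amp_threshold) next
    rise_seg <- xs[i:(i + p_rel - 1)] - base
    if (length(rise_seg) >= 2) {
      t10 <- approx(rise_seg, seq_along(rise_seg), xout = 0.1 * amp,
                    ties = "ordered")$y
      t90 <- approx(rise_seg, seq_along(rise_seg), xout = 0.9 * amp,
                    ties = "ordered")$y
    } else t10 <- t90 <- NA_real_
    rows[[length(rows) + 1L]] <-
      data.frame(onset_t = (i - 1) * dt, peak_t = (i + p_rel - 2) * dt,
                 peak_amplitude = amp,
                 rise_10_90 = if (is.na(t10) || is.na(t90)) NA_real_ else
                   (t90 - t10) * dt)
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset_t = numeric(0), peak_t = numeric(0),
               peak_amplitude = numeric(0), rise_10_90 = numeric(0))
  out <- list(events = events, frequency = nrow(events) / dur_s,
              duration_s = dur_s,
              settings = list(polarity = polarity,
                              amp_threshold = amp_threshold,
                              deriv_k = deriv_k, refractory_ms = refractory_ms,
                              smooth_ms = smooth_ms, noise_sd = noise_sd))
  class(out) <- "fsi_events"
  out
}
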