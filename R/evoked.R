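# Evoked-EPSC analysis: success/failure classification, averaging,
# amplitude/rise/charge metrics, bi-exponential decay fits with weighted tau,
# and drug-block quantification.

#' Average evoked responses under minimal stimulation
#'
#' Segments a pulse-train sweep (or a set of single-pulse sweeps) into
#' per-pulse epochs, classifies each as success or failure by the
#' baseline-noise criterion (peak within the success window exceeding
#' `noise_k` x baseline SD), and averages the successes.
#'
#' @param sweep_set Voltage-clamp `fsi_sweep_set` whose sweeps carry
#'   `meta$pulse_times`.
#' @param window_ms Epoch length after each pulse (ms).
#' @param baseline_ms Pre-pulse baseline (ms).
#' @param success_window_ms Post-pulse window searched for the success
#'   peak (ms); widen for slow NMDA responses.
#' @param noise_k Success criterion in baseline SDs.
#' @param max_n Average at most this many successes (e.g. 10 to mirror
#'   5-10-response averages); `NULL` for all.
#' @param include_failures Average failures too (off by default).
#' @param polarity `"auto"`, `"negative"` or `"positive"`.
#' @return List of class `fsi_mean_trace`: `t` (ms, 0 at pulse), `current`
#'   (pA, baseline-subtracted), `failure_rate`, `n_averaged`, `n_pulses`,
#'   `polarity`, `sampling_khz`.
#' @export
average_evoked <- function(sweep_set, window_ms = 600, baseline_ms = 50,
                           success_window_ms = c(1, 10), noise_k = 3,
                           max_n = NULL, include_failures = FALSE,
                           polarity = "auto") {
  epochs <- list(); n_pulses <- 0L
  khz <- sweep_set[[1]]$sampling_khz
  nb <- round(baseline_ms * khz); nw <- round(window_ms * khz)
  for (s in sweep_set$sweeps) {
    assert_mode(s, "voltage_clamp")
    for (pt in s$meta$pulse_times) {
      i0 <- round(pt * khz) + 1L
      if (i0 - nb < 1 || i0 + nw > length(s$signal)) next
      n_pulses <- n_pulses + 1L
      epochs[[n_pulses]] <- s$signal[(i0 - nb):(i0 + nw)]
    }
  }
  if (n_pulses < 5)
    fsi_error("need >= 5 pulses with a known pulse time",
              "insufficient_protocol")
  m <- do.call(rbind, epochs)
  # classification uses a lightly smoothed copy so the peak-vs-noise test is
  # not dominated by the single-sample noise maximum over a wide window
  wsm <- max(1L, round(1 * khz))
  ker <- rep(1 / wsm, wsm)
  msm <- t(apply(m, 1, function(r) {
    y <- as.numeric(stats::filter(r, ker, sides = 2))
    y[is.na(y)] <- r[is.na(y)]
    y
  }))
  nb0 <- max(1L, nb - wsm)   # keep the smoothed response edge out of baseline
  base <- rowMeans(msm[, 1:nb0, drop = FALSE])
  base_sd <- apply(msm[, 1:nb0, drop = FALSE], 1, sd)
  sub <- m - base
  subsm <- msm - base
  if (polarity == "auto") {
    iw <- nb + round(success_window_ms[1] * khz):round(success_window_ms[2] * khz)
    polarity <- if (mean(sub[, iw]) < 0) "negative" else "positive"
  }
  sgn <- if (polarity == "negative") -1 else 1
  iw <- (nb + round(success_window_ms[1] * khz)):(nb + round(success_window_ms[2] * khz))
  pk <- apply(sgn * subsm[, iw, drop = FALSE], 1, max)
  success <- pk > noise_k * base_sd
  failure_rate <- 1 - mean(success)
  use <- if (include_failures) seq_len(n_pulses) else which(success)
  if (!length(use))
    fsi_error("all pulses classified as failures; no response to average",
              "no_response")
  if (!is.null(max_n)) use <- head(use, max_n)
  avg <- colMeans(sub[use, , drop = FALSE])
  out <- list(t = (seq_along(avg) - 1 - nb) / khz, current = avg,
              failure_rate = failure_rate, n_averaged = length(use),
              n_pulses = n_pulses, polarity = polarity, sampling_khz = khz)
  class(out) <- "fsi_mean_trace"
  out
}

#' Amplitude, rise time and charge of an averaged EPSC
#'
#' Peak amplitude is measured from the (already subtracted) baseline to the
#' extremum after the pulse; the 10-90% rise time is interpolated between
#' the 10% and 90% amplitude points; charge is the trapezoidal integral of
#' the baseline-subtracted current over the integration window.
#'
#' @param mean_trace `fsi_mean_trace` from [average_evoked()].
#' @param integration_window_ms Charge window after the pulse (ms); 500 for
#'   NMDA, 50 for AMPA by convention.
#' @return List: `peak_amplitude` (pA, positive magnitude), `peak_t` (ms),
#'   `rise_10_90` (ms), `charge_Q` (pA.ms, positive magnitude), `polarity`.
#' @export
evoked_metrics <- function(mean_trace, integration_window_ms = 500) {
  t <- mean_trace$t; y <- mean_trace$current
  sgn <- if (mean_trace$polarity == "negative") -1 else 1
  x <- sgn * y
  post <- which(t >= 0 & t <= integration_window_ms)
  p_rel <- which.max(x[post]); p <- post[p_rel]
  amp <- x[p]
  rise_idx <- post[1]:p
  xr <- x[rise_idx]
  if (length(xr) >= 2) {
    t10 <- approx(xr, t[rise_idx], xout = 0.1 * amp, ties = "ordered")$y
    t90 <- approx(xr, t[rise_idx], xout = 0.9 * amp, ties = "ordered")$y
  } else t10 <- t90 <- NA_real_
  q <- trapz_q(t[post], x[post])
  list(peak_amplitude = amp, peak_t = t[p],
       rise_10_90 = if (is.na(t10) || is.na(t90)) NA_real_ else t90 - t10,
       charge_Q = q, polarity = mean_trace$polarity)
}

#' Amplitude-weighted decay constant
#'
#' `tau_W = (A1 tau1 + A2 tau2) / (A1 + A2)`.
#'
#' @param A1,tau1,A2,tau2 Amplitudes and time constants of the two decay
#'   components.
#' @return Weighted tau (ms).
#' @export
tau_weighted <- function(A1, tau1, A2, tau2) {
  (A1 * tau1 + A2 * tau2) / (A1 + A2)
}

# Deterministic starts from log-linear fits to the early and late thirds of
# the decay.
#' @noRd
biexp_starts <- function(t, y) {
  n <- length(t)
  late <- (2 * n %/% 3):n
  lf <- lm(log(pmax(y[late], max(y) * 1e-6)) ~ t[late])
  tau2 <- -1 / coef(lf)[[2]]
  A2 <- exp(coef(lf)[[1]])
  if (!is.finite(tau2) || tau2 <= 0) { tau2 <- diff(range(t)) / 2; A2 <- y[1] / 2 }
  resid <- y - A2 * exp(-t / tau2)
  early <- 1:max(3, n %/% 3)
  pos <- resid[early] > 0
  tau1 <- tau2 / 5; A1 <- max(y[1] - A2, y[1] * 0.05)
  if (sum(pos) >= 3) {
    ef <- lm(log(resid[early][pos]) ~ t[early][pos])
    if (is.finite(coef(ef)[[2]]) && coef(ef)[[2]] < 0) {
      tau1 <- -1 / coef(ef)[[2]]
      A1 <- exp(coef(ef)[[1]])
    }
  }
  list(A1 = A1, tau1 = min(tau1, tau2 * 0.9), A2 = A2, tau2 = tau2)
}

#' Fit a bi-exponential decay
#'
#' Nonlinear least squares fit of `A1 exp(-t/tau1) + A2 exp(-t/tau2)` to a
#' decay segment starting at the peak, from multiple deterministic starts
#' (log-linear fits to the early/late thirds, plus fixed perturbations).
#' When the two time constants collapse, a single-exponential fallback is
#' fitted and flagged.
#'
#' @param t Time from the peak (ms), increasing from 0.
#' @param y Decay values (positive magnitudes, peak first).
#' @param min_len Minimum number of samples.
#' @return List of class `fsi_biexp_fit`: `A1`, `tau1`, `A2`, `tau2` (with
#'   `tau1 <= tau2`), `tau_W`, `single_exponential`, `residual_norm`,
#'   `converged`.
#' @export
fit_biexponential <- function(t, y, min_len = 50) {
  if (length(t) < min_len)
    fsi_error("decay segment too short for a reliable bi-exponential fit",
              "insufficient_protocol")
  sgn <- if (mean(y) < 0) -1 else 1
  y <- sgn * y
  s0 <- biexp_starts(t, y)
  starts <- list(
    s0,
    list(A1 = s0$A1, tau1 = s0$tau1 / 2, A2 = s0$A2, tau2 = s0$tau2),
    list(A1 = s0$A1, tau1 = s0$tau1, A2 = s0$A2, tau2 = s0$tau2 * 2),
    list(A1 = y[1] * 0.7, tau1 = max(t) / 20, A2 = y[1] * 0.3,
         tau2 = max(t) / 3)
  )
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2),
                        start = modifyList(st, list(
                          tau1 = min(st$tau1, 9 * max(t)),
                          tau2 = min(st$tau2, 9 * max(t)))),
                        lower = c(A1 = 0, tau1 = 1e-3, A2 = 0, tau2 = 1e-3),
                        upper = c(A1 = Inf, tau1 = 10 * max(t),
                                  A2 = Inf, tau2 = 10 * max(t)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rn <- sqrt(sum(stats::residuals(fit)^2))
      if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
    }
  }
  single <- FALSE
  if (is.null(best)) {
    # all bi-exponential starts singular: the decay is effectively
    # mono-exponential; fall through to the flagged fallback
    cf <- c(A1 = y[1], tau1 = s0$tau2, A2 = 0, tau2 = s0$tau2)
    best <- list(fit = NULL, rn = Inf)
    single <- NA
  } else {
    cf <- coef(best$fit)
  }
  # order components fast -> slow
  if (cf[["tau1"]] > cf[["tau2"]])
    cf <- c(A1 = cf[["A2"]], tau1 = cf[["tau2"]],
            A2 = cf[["A1"]], tau2 = cf[["tau1"]])
  if (is.na(single) ||
      abs(cf[["tau2"]] - cf[["tau1"]]) / cf[["tau2"]] < 0.05 ||
      cf[["A1"]] < 1e-3 * cf[["A2"]] || cf[["A2"]] < 1e-3 * cf[["A1"]]) {
    single <- FALSE
    sf <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-t / tau),
                        start = list(A = y[1],
                                     tau = max(cf[["tau2"]], 1e-2)),
                        lower = c(A = 0, tau = 1e-3)),
      error = function(e) NULL)
    if (!is.null(sf)) {
      single <- TRUE
      cs <- coef(sf)
      cf <- c(A1 = cs[["A"]], tau1 = cs[["tau"]], A2 = 0, tau2 = cs[["tau"]])
      best <- list(fit = sf, rn = sqrt(sum(stats::residuals(sf)^2)))
    }
  }
  if (!is.finite(best$rn) && !single)
    fsi_error("bi-exponential fit failed to converge from all starts",
              "fit_failure")
  out <- list(A1 = cf[["A1"]], tau1 = cf[["tau1"]], A2 = cf[["A2"]],
              tau2 = cf[["tau2"]],
              tau_W = tau_weighted(cf[["A1"]], cf[["tau1"]],
                                   cf[["A2"]], cf[["tau2"]]),
              single_exponential = single, residual_norm = best$rn,
              converged = TRUE)
  class(out) <- "fsi_biexp_fit"
  out
}

#' Full evoked-EPSC characterization
#'
#' Convenience wrapper: metrics plus bi-exponential decay fit of the mean
#' trace.
#'
#' @param mean_trace `fsi_mean_trace`.
#' @param integration_window_ms Charge window (ms).
#' @param decay_window_ms Length of decay fitted after the peak (ms);
#'   default the integration window.
#' @return List of class `fsi_evoked_fit` combining [evoked_metrics()] and
#'   [fit_biexponential()] fields, plus `failure_rate` and `n_averaged`.
#' @export
evoked_fit <- function(mean_trace, integration_window_ms = 500,
                       decay_window_ms = integration_window_ms) {
  met <- evoked_metrics(mean_trace, integration_window_ms)
  sgn <- if (mean_trace$polarity == "negative") -1 else 1
  sel <- mean_trace$t >= met$peak_t &
    mean_trace$t <= met$peak_t + decay_window_ms
  fit <- fit_biexponential(mean_trace$t[sel] - met$peak_t,
                           sgn * mean_trace$current[sel])
  out <- c(met, unclass(fit),
           list(failure_rate = mean_trace$failure_rate,
                n_averaged = mean_trace$n_averaged))
  class(out) <- "fsi_evoked_fit"
  out
}

#' Quantify drug block of an evoked current
#'
#' Percent reductions in peak amplitude and total charge, and percent change
#' in the weighted decay constant (positive = faster decay after the drug).
#'
#' @param pre,post Fits (lists with `peak_amplitude`, `charge_Q`, `tau_W`),
#'   positive-magnitude convention.
#' @return List of class `fsi_block_result`: `pct_peak_reduction`,
#'   `pct_Q_reduction`, `pct_change_tauW` (all %).
#' @export
quantify_block <- function(pre, post) {
  if (!is_scalar_number(pre$peak_amplitude) || pre$peak_amplitude <= 0)
    fsi_error("pre-drug peak must be > 0", "undefined_reference")
  out <- list(
    pct_peak_reduction = 100 * (pre$peak_amplitude - post$peak_amplitude) /
      pre$peak_amplitude,
    pct_Q_reduction = 100 * (pre$charge_Q - post$charge_Q) / pre$charge_Q,
    pct_change_tauW = 100 * (pre$tau_W - post$tau_W) / pre$tau_W)
  class(out) <- "fsi_block_result"
  out
}

#' Check pharmacological isolation labels on a sweep
#'
#' Sweeps labeled `"NMDA"` must carry the glycine + DNQX + SR95531 tags and
#' be held at +60 mV; sweeps labeled `"AMPA"` must be held at -60 mV.
#'
#' @param sweep Voltage-clamp `fsi_sweep`.
#' @return `TRUE` (invisibly) on pass; otherwise an error of class
#'   `fsiephys_labeled_condition` naming the mismatch.
#' @export
nmda_isolation_check <- function(sweep) {
  lab <- sweep$conditions$label %||% ""
  hold <- sweep$meta$holding
  if (identical(lab, "NMDA")) {
    need <- c("glycine", "DNQX", "SR95531")
    missing_tags <- setdiff(need, sweep$conditions$tags %||% character(0))
    if (length(missing_tags))
      fsi_error(paste0("NMDA-isolated sweep missing condition tags: ",
                       paste(missing_tags, collapse = ", ")),
                "labeled_condition")
    if (!isTRUE(all.equal(hold, 60)))
      fsi_error(sprintf("NMDA-isolated sweep held at %g mV, expected +60 mV",
                        hold), "labeled_condition")
  } else if (identical(lab, "AMPA")) {
    if (!isTRUE(all.equal(hold, -60)))
      fsi_error(sprintf("AMPA sweep held at %g mV, expected -60 mV", hold),
                "labeled_condition")
  } else {
    fsi_error("sweep carries no NMDA/AMPA condition label",
              "labeled_condition")
  }
  invisible(TRUE)
}
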