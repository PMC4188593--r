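# Passive membrane properties from hyperpolarizing current steps.

#' Measure passive membrane properties
#'
#' From a hyperpolarizing step family (600 ms steps including -300 pA):
#' resting potential (pre-stimulus baseline of the earliest sweep), input
#' resistance (regression slope of steady-state voltage deflection on
#' injected current across all hyperpolarizing steps), membrane time constant
#' (single-exponential fit to the initial relaxation of the -300 pA sweep),
#' and sag (end-of-step voltage minus maximal hyperpolarization on the
#' -300 pA sweep).
#'
#' @param sweep_set Current-clamp `fsi_sweep_set` containing at least two
#'   hyperpolarizing steps, one of them -300 pA.
#' @param steady_window Window before step end used for the steady-state
#'   voltage (ms).
#' @return List with `V_rest` (mV), `R_in` (MOhm), `tau_m` (ms), `sag_Ih`
#'   (mV), and the per-sweep table `steps`.
#' @export
measure_passive <- function(sweep_set, steady_window = 50) {
  amps <- vapply(sweep_set$sweeps, function(s) s$meta$amplitude, numeric(1))
  hyp <- which(amps < 0)
  if (length(hyp) < 2)
    fsi_error("need >= 2 hyperpolarizing steps", "insufficient_protocol")
  if (!any(amps[hyp] == -300))
    fsi_error("need a -300 pA step for tau_m and sag", "insufficient_protocol")

  s1 <- sweep_set[[1]]
  khz <- s1$sampling_khz
  onset <- s1$meta$step_onset
  dur <- s1$meta$step_duration
  i_on <- round(onset * khz)
  i_off <- round((onset + dur) * khz)
  v_rest <- mean(s1$signal[1:i_on])

  steps <- do.call(rbind, lapply(hyp, function(k) {
    s <- sweep_set[[k]]
    base <- mean(s$signal[1:i_on])
    vss <- mean(s$signal[(i_off - round(steady_window * khz)):i_off])
    data.frame(amplitude = amps[k], V_base = base, V_steady = vss,
               dV = vss - base)
  }))
  slope <- coef(lm(dV ~ amplitude, data = steps))[["amplitude"]]  # mV/pA
  r_in <- slope * 1000                                             # MOhm

  s300 <- sweep_set[[hyp[which(amps[hyp] == -300)[1]]]]
  seg <- s300$signal[i_on:i_off]
  trough_i <- which.min(seg)
  v_end <- mean(s300$signal[(i_off - round(steady_window * khz)):i_off])
  sag <- v_end - seg[trough_i]

  # tau_m from the initial relaxation (onset to trough)
  fit_n <- max(trough_i, round(5 * khz))
  tt <- (seq_len(fit_n) - 1) / khz
  yy <- s300$signal[(i_on + 1):(i_on + fit_n)]
  fit <- tryCatch(nls(yy ~ SSasymp(tt, Asym, R0, lrc)),
                  error = function(e) NULL)
  tau <- if (is.null(fit)) NA_real_ else 1 / exp(coef(fit)[["lrc"]])
  if (!is.finite(tau)) {
    # log-linear fallback (exact on noiseless single-exponential relaxation)
    vinf <- mean(tail(yy, round(fit_n / 10)))
    dev <- yy - vinf
    use <- which(abs(dev) > 0.02 * abs(dev[1]))
    if (length(use) > 10 && all(sign(dev[use]) == sign(dev[use][1]))) {
      lf <- lm(log(abs(dev[use])) ~ tt[use])
      if (is.finite(coef(lf)[[2]]) && coef(lf)[[2]] < 0)
        tau <- -1 / coef(lf)[[2]]
    }
  }

  list(V_rest = v_rest, R_in = r_in, tau_m = tau, sag_Ih = sag, steps = steps)
}
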