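# Spike detection, phase plots, passive properties, rheobase, latency
# regimes, threshold dynamics and train features.

test_that("a constant trace contains no spikes", {
  sw <- new_sweep(rep(-65, 2000), numeric(2000), 20, "current_clamp",
                  meta = list(step_onset = 10, step_duration = 50))
  expect_equal(nrow(detect_spikes(sw)), 0)
})

test_that("detect_spikes rejects voltage-clamp sweeps", {
  sw <- new_sweep(numeric(100), numeric(100), 20, "voltage_clamp")
  expect_error(detect_spikes(sw), class = "fsiephys_wrong_mode")
})

test_that("threshold matches a brute-force finite-difference scan on planted spikes", {
  sw <- synthetic_spike_sweep(c(150, 300, 450.37))
  got <- detect_spikes(sw)
  ref <- oracle_spikes(sw$signal, 1 / sw$sampling_khz)
  expect_equal(nrow(got), 3)
  expect_equal(got$threshold_t, ref$threshold_t)
  expect_equal(got$threshold_V, ref$threshold_V)
  expect_equal(got$peak_t, ref$peak_t)
  expect_equal(got$half_width, ref$half_width)
})

test_that("spike features match the naive reference on simulated sweeps, exactly", {
  set.seed(7)
  for (k in 1:10) {
    p <- fsi_params(sample(c("vehicle", "mk801"), 1),
                    noise_sigma = runif(1, 0, 3))
    amp <- sample(120:420, 1)
    sw <- simulate_current_clamp(p, step_protocol(amp, sweep_duration = 500),
                                 seed = k)[[1]]
    got <- detect_spikes(sw)
    ref <- oracle_spikes(sw$signal, 1 / sw$sampling_khz)
    expect_identical(nrow(got), nrow(ref))
    expect_identical(got$threshold_t, ref$threshold_t)
    expect_identical(got$threshold_V, ref$threshold_V)
    expect_identical(got$half_width, ref$half_width)
  }
})

test_that("slow criterion crossings without an upstroke are not spikes; weak-baseline crossings are flagged", {
  # 15 mV/ms ramp crosses the criterion but never produces a spike
  khz <- 20
  v <- c(rep(-65, 200), seq(-65, -50, length.out = 20), rep(-50, 400))
  sw <- new_sweep(v, numeric(length(v)), khz, "current_clamp",
                  meta = list(step_onset = 10, step_duration = 20))
  expect_equal(nrow(detect_spikes(sw)), 0)
  # spike riding on a wobbly baseline fails the 20-fold rule and is flagged
  set.seed(1)
  n <- 3000
  base <- -65 + cumsum(rnorm(n, 0, 0.05))
  sw2 <- synthetic_spike_sweep(100)
  sw2$signal[1:n] <- sw2$signal[1:n] + (base - -65)
  sp <- detect_spikes(sw2)
  expect_equal(nrow(sp), 1)
  expect_false(sp$valid[1])
})

test_that("phase plots follow calculus on ramps and sinusoids", {
  khz <- 20
  tt <- seq(0, 100 - 1 / khz, by = 1 / khz)
  ramp <- new_sweep(tt, numeric(length(tt)), khz, "current_clamp")
  pp <- phase_plot(ramp)
  expect_true(all(abs(pp$dVdt - 1) < 1e-9))

  f <- 0.05  # kHz -> omega = 2 pi f (rad/ms)
  A <- 30
  sine <- new_sweep(A * sin(2 * pi * f * tt), numeric(length(tt)), khz,
                    "current_clamp")
  ps <- phase_plot(sine)
  expect_equal(max(abs(ps$dVdt)), A * 2 * pi * f, tolerance = 0.01)
})

test_that("phase-plot threshold agrees with detect_spikes within one sample step", {
  p <- fsi_params("vehicle", noise_sigma = 0)
  sw <- simulate_current_clamp(p, step_protocol(250, sweep_duration = 400),
                               seed = 1)[[1]]
  sp <- detect_spikes(sw)
  thr_pp <- phase_threshold(phase_plot(sw))
  i <- which(sweep_time(sw) == sp$threshold_t[1])
  dV_sample <- abs(diff(sw$signal))[c(i - 1, i)]
  expect_lte(abs(thr_pp - sp$threshold_V[1]), max(dV_sample) + 1e-9)
})

test_that("passive measurement recovers an ideal RC cell within 1%", {
  p <- rc_params(R = 103, tau = 6.8)
  ss <- simulate_current_clamp(p, step_protocol(c(-300, -150, -100, -50)),
                               seed = 1)
  pv <- measure_passive(ss)
  expect_equal(pv$R_in, 103, tolerance = 0.01)
  expect_equal(pv$tau_m, 6.8, tolerance = 0.01)
  expect_equal(pv$V_rest, -65, tolerance = 1e-3)
  # Ohm's law on the -300 pA step
  s300 <- ss[[1]]
  i_off <- round((s300$meta$step_onset + 600) * s300$sampling_khz)
  dv <- mean(s300$signal[(i_off - 1000):i_off]) - pv$V_rest
  expect_equal(dv, -30.9, tolerance = 0.01)
})

test_that("sag is the end-of-step voltage minus the maximal hyperpolarization", {
  khz <- 20
  onset <- 100; dur <- 600
  n <- round(1000 * khz)
  v <- rep(-65, n)
  i_on <- round(onset * khz); i_off <- round((onset + dur) * khz)
  seg <- seq(i_on + 1, i_off)
  # drop to -90, relax to a flat -86
  drop <- seq(-65, -90, length.out = 2000)
  relax <- -86 - 4 * exp(-(seq_along(seg) - 2000)[-(1:2000)] / 500)
  v[seg] <- c(drop, relax)
  stim <- numeric(n); stim[seg] <- -300
  sw <- new_sweep(v, stim, khz, "current_clamp",
                  meta = list(step_onset = onset, step_duration = dur,
                              amplitude = -300))
  v2 <- rep(-65, n); v2[seg] <- -80
  sw2 <- new_sweep(v2, stim * 0.5, khz, "current_clamp",
                   meta = list(step_onset = onset, step_duration = dur,
                               amplitude = -150))
  pv <- measure_passive(new_sweep_set(list(sw, sw2), NULL))
  expect_equal(pv$sag_Ih, 4.0, tolerance = 0.01)
})

test_that("passive measurement demands hyperpolarizing steps", {
  p <- fsi_params("vehicle", noise_sigma = 0)
  ss <- simulate_current_clamp(p, step_protocol(c(50, 100)), seed = 1)
  expect_error(measure_passive(ss), class = "fsiephys_insufficient_protocol")
})

test_that("rheobase search returns the smallest single-spike amplitude", {
  provider <- function(amp, trial)
    synthetic_spike_sweep(if (amp >= 140) 400 else numeric(0))
  rb <- find_rheobase(provider, start_pA = 120, increment = 1)
  expect_equal(rb$I_th, 140)
  expect_s3_class(rb$latency_sweep, "fsi_sweep")

  # coarser grid can only overshoot, by less than its increment
  rb5 <- find_rheobase(provider, start_pA = 123, increment = 5)
  expect_gte(rb5$I_th, rb$I_th)
  expect_lt(rb5$I_th - rb$I_th, 5)
})

test_that("cells that never fire a single spike are excluded; silent scans signal not-found", {
  burster <- function(amp, trial)
    synthetic_spike_sweep(if (amp >= 100) c(200, 250, 300) else numeric(0))
  expect_error(find_rheobase(burster, 90, 5, max_pA = 200),
               class = "fsiephys_excluded_cell")
  silent <- function(amp, trial) synthetic_spike_sweep(numeric(0))
  err <- tryCatch(find_rheobase(silent, 50, 5, max_pA = 80),
                  error = function(e) e)
  expect_s3_class(err, "fsiephys_rheobase_not_found")
  expect_true(is.data.frame(err$scan))
})

test_that("rheobase increments outside 1-5 pA are rejected", {
  provider <- function(amp, trial) synthetic_spike_sweep(400)
  expect_error(find_rheobase(provider, 50, increment = 10),
               class = "fsiephys_invalid_protocol")
  expect_error(step_protocol(100, increment = 0.5),
               class = "fsiephys_invalid_protocol")
})

test_that("first-spike latency is threshold time minus stimulus onset", {
  # offset of the criterion crossing within the spike template
  c_off <- detect_spikes(synthetic_spike_sweep(300))$threshold_t[1] - 300
  sw <- synthetic_spike_sweep(100 + 12.5 - c_off)
  sp <- detect_spikes(sw)
  expect_equal(first_spike_latency(sw), sp$threshold_t[1] - 100)
  expect_equal(first_spike_latency(sw), 12.5, tolerance = 0.051)
  empty <- synthetic_spike_sweep(numeric(0))
  expect_error(first_spike_latency(empty), class = "fsiephys_no_spike")
})

test_that("latency equals detect_spikes threshold minus onset on simulated sweeps", {
  set.seed(11)
  for (k in 1:10) {
    p <- fsi_params("vehicle", noise_sigma = 2)
    amp <- sample(150:400, 1)
    sw <- simulate_current_clamp(p, step_protocol(amp, sweep_duration = 500),
                                 seed = k)[[1]]
    sp <- detect_spikes(sw)
    if (nrow(sp) == 0) next
    expect_equal(first_spike_latency(sw), sp$threshold_t[1] - 100)
  }
})

test_that("latency-current regimes: power law, constant latencies, sparse regimes", {
  ith <- 100
  amps <- c(110, 130, 150, 180, 230, 260, 300, 350)
  c_off <- detect_spikes(synthetic_spike_sweep(300))$threshold_t[1] - 300
  # latencies exactly proportional to 1/I
  sweeps <- lapply(amps, function(a)
    synthetic_spike_sweep(100 + 4000 / a - c_off, amplitude = a))
  ss <- new_sweep_set(sweeps, NULL)
  lc <- latency_current_curve(ss, ith)
  expect_equal(lc$low_slope, -1, tolerance = 0.01)

  # identical latencies: slope 0, CV 0, floor present
  sweeps2 <- lapply(amps, function(a)
    synthetic_spike_sweep(120 - c_off, amplitude = a))
  lc2 <- latency_current_curve(new_sweep_set(sweeps2, NULL), ith)
  expect_equal(lc2$low_slope, 0, tolerance = 1e-9)
  expect_equal(lc2$high_cv, 0, tolerance = 1e-9)
  expect_true(lc2$floor_present)

  # fewer than 3 points in the high regime: not evaluable
  lc3 <- latency_current_curve(new_sweep_set(sweeps[1:5], NULL), ith)
  expect_false(lc3$high_evaluable)
  expect_true(is.na(lc3$floor_present))
})

test_that("threshold dynamics recovers a constructed slope and matches normal equations", {
  ith <- 150
  offs <- seq(0, 300, 50)
  # thresholds rising 0.018 mV/pA: shift each sweep's baseline so the
  # template's crossing voltage moves linearly with amplitude
  sweeps <- lapply(offs, function(o)
    synthetic_spike_sweep(150, baseline = -65 + 0.018 * o,
                          amplitude = ith + o))
  td <- threshold_dynamics(new_sweep_set(sweeps, NULL))
  expect_equal(td$slope, 0.018, tolerance = 1e-6)
  pts <- td$points
  expect_equal(td$slope, oracle_ols_slope(pts$amplitude, pts$threshold_V),
               tolerance = 1e-10)

  # constant thresholds give slope 0; spikeless sweeps are counted
  sweeps0 <- lapply(offs, function(o)
    synthetic_spike_sweep(if (o < 300) 150 else numeric(0),
                          amplitude = ith + o))
  td0 <- threshold_dynamics(new_sweep_set(sweeps0, NULL))
  expect_equal(td0$slope, 0)
  expect_equal(td0$n_omitted, 1L)
})

test_that("threshold-dynamics OLS equals the normal-equations oracle on simulated cells", {
  p <- fsi_params("mk801", noise_sigma = 2)
  ss <- simulate_current_clamp(p, step_protocol(55 + seq(0, 300, 50)),
                               seed = 3)
  td <- threshold_dynamics(ss)
  use <- td$points[is.finite(td$points$threshold_V), ]
  expect_equal(td$slope, oracle_ols_slope(use$amplitude, use$threshold_V),
               tolerance = 1e-10)
})

test_that("train features: regular and accelerating trains, short trains", {
  reg <- synthetic_spike_sweep(seq(150, 550, by = 25))
  tf <- train_features(reg)
  expect_equal(tf$accommodation_ratio_ISI, 1.0, tolerance = 1e-9)
  expect_equal(tf$amp_ratio_1st_2nd, 1.0, tolerance = 1e-9)
  expect_equal(tf$max_spike_freq, length(seq(150, 550, 25)) / 0.6)

  # ISIs 10, 12, 14, 16, 18 ms -> ratio 10 / mean(14, 16, 18) = 0.625
  times <- 150 + cumsum(c(0, 10, 12, 14, 16, 18))
  tf2 <- train_features(synthetic_spike_sweep(times))
  expect_equal(tf2$accommodation_ratio_ISI, 0.625, tolerance = 1e-9)

  short <- synthetic_spike_sweep(c(150, 200, 250))
  tf3 <- train_features(short)
  expect_true(is.na(tf3$accommodation_ratio_ISI))
  expect_match(tf3$reason, "fewer than 5")
})
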