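# Spontaneous-event detection, evoked averaging and metrics, bi-exponential
# fitting, weighted tau, and block quantification.

test_that("planted template events are each detected exactly once", {
  times <- seq(40, 4990, length.out = 100)
  sw <- synthetic_event_sweep(times, amp = -50, duration_ms = 5000)
  ev <- detect_events(sw, "negative", amp_threshold = 10, enforce_min = FALSE)
  expect_equal(nrow(ev$events), 100)
  expect_equal(ev$frequency, 20)
  expect_true(all(ev$events$peak_amplitude > 40))
})

test_that("an empty trace yields zero events", {
  sw <- synthetic_event_sweep(numeric(0), duration_ms = 12000)
  ev <- detect_events(sw, "negative", amp_threshold = 5)
  expect_equal(ev$frequency, 0)
})

test_that("detection requires a voltage-clamp sweep and sufficient duration", {
  cc <- new_sweep(numeric(1000), numeric(1000), 20, "current_clamp")
  expect_error(detect_events(cc, "negative"), class = "fsiephys_wrong_mode")
  short <- synthetic_event_sweep(numeric(0), duration_ms = 2000)
  expect_error(detect_events(short, "negative"),
               class = "fsiephys_insufficient_protocol")
})

test_that("Poisson trains at 26 Hz are recovered within 2 Hz", {
  p <- fsi_params("vehicle")
  syn <- synaptic_params("vehicle", rate_sEPSC = 26, rate_sIPSC = 0,
                         frac_nmda_only = 0)
  f <- vapply(1:4, function(sd) {
    ss <- simulate_voltage_clamp(p, syn, vc_protocol(-40, 120000), seed = sd)
    detect_events(ss[[1]], "negative")$frequency
  }, numeric(1))
  expect_true(all(abs(f - 26) <= 2))
})

test_that("removing Mg2+ strictly increases detected sEPSCs when NMDA is present, and not otherwise", {
  p <- fsi_params("vehicle")
  syn <- synaptic_params("vehicle", rate_sIPSC = 0)
  n_at_mg <- vapply(c(2, 0), function(mg) {
    s <- syn; s$Mg_mM <- mg
    ss <- simulate_voltage_clamp(p, s, vc_protocol(-40, 60000), seed = 21)
    nrow(detect_events(ss[[1]], "negative")$events)
  }, numeric(1))
  expect_gt(n_at_mg[2], n_at_mg[1])

  ampa_only <- synaptic_params("vehicle", g_NMDA = 0, rate_sIPSC = 0,
                               tau_decay_NMDA_B = 109)
  tr <- lapply(c(2, 0), function(mg) {
    s <- ampa_only; s$Mg_mM <- mg
    simulate_voltage_clamp(p, s, vc_protocol(-40, 60000), seed = 21)[[1]]
  })
  expect_identical(tr[[1]]$signal, tr[[2]]$signal)
})

test_that("failure classification recovers planted failures and averages successes", {
  # 10 epochs, 5 with a response, low noise
  khz <- 20
  times <- seq(100, by = 500, length.out = 10)
  resp <- times[c(1, 3, 5, 7, 9)]
  sw <- synthetic_event_sweep(resp, amp = -80, duration_ms = 5200,
                              noise = 0.5)
  sw$meta$pulse_times <- times
  ss <- new_sweep_set(list(sw), NULL)
  mt <- average_evoked(ss, window_ms = 300, baseline_ms = 40)
  expect_equal(mt$failure_rate, 0.5)
  expect_equal(mt$n_averaged, 5)

  # identical success sweeps: the mean equals any single epoch
  sw2 <- synthetic_event_sweep(times, amp = -80, duration_ms = 5200)
  sw2$meta$pulse_times <- times
  mt2 <- average_evoked(new_sweep_set(list(sw2), NULL), window_ms = 300,
                        baseline_ms = 40)
  i0 <- round(times[1] * khz) + 1L
  epoch1 <- sw2$signal[(i0 - round(40 * khz)):(i0 + round(300 * khz))]
  expect_equal(mt2$current, epoch1, tolerance = 1e-12)

  # all failures -> no-response signal
  sw3 <- synthetic_event_sweep(numeric(0), duration_ms = 5200, noise = 0.5)
  sw3$meta$pulse_times <- times
  expect_error(average_evoked(new_sweep_set(list(sw3), NULL),
                              window_ms = 300),
               class = "fsiephys_no_response")
})

test_that("simulated minimal stimulation lands in the binomial failure band", {
  p <- fsi_params("vehicle", noise_sigma = 1)
  syn <- synaptic_params("vehicle", rate_sEPSC = 0, rate_sIPSC = 0)
  prot <- vc_protocol(-60, duration = 100 * 300 + 200, n_pulses = 100,
                      pulse_period = 300)
  ss <- simulate_voltage_clamp(p, syn, prot, seed = 4)
  mt <- average_evoked(ss, window_ms = 100, baseline_ms = 30)
  expect_gte(mt$failure_rate, 0.38)
  expect_lte(mt$failure_rate, 0.62)
  expect_lte(abs(mt$failure_rate - mean(ss[[1]]$meta$failures)), 0.03)
})

test_that("evoked metrics follow geometry: rectangles, exponentials, ramps", {
  khz <- 20
  nb <- round(50 * khz)
  mk_trace <- function(y) {
    structure(list(t = (seq_along(y) - 1 - nb) / khz, current = y,
                   failure_rate = 0, n_averaged = 1, n_pulses = 1,
                   polarity = "positive", sampling_khz = khz),
              class = "fsi_mean_trace")
  }
  # 100 pA x 10 ms rectangle: peak 100, Q = 1000 pA.ms
  y <- c(numeric(nb), rep(100, round(10 * khz)), numeric(round(200 * khz)))
  m <- evoked_metrics(mk_trace(y), integration_window_ms = 150)
  expect_equal(m$peak_amplitude, 100)
  expect_equal(m$charge_Q, 1000, tolerance = 0.005)

  # exponential decay: Q = A tau
  tt <- seq(0, 500, by = 1 / khz)
  y2 <- c(numeric(nb), 100 * exp(-tt / 50))
  m2 <- evoked_metrics(mk_trace(y2), integration_window_ms = 500)
  expect_equal(m2$charge_Q, 5000, tolerance = 0.01)

  # linear ramp of duration d: 10-90% rise = 0.8 d
  d <- 20
  y3 <- c(numeric(nb), seq(0, 100, length.out = round(d * khz)),
          rep(100, round(50 * khz)))
  m3 <- evoked_metrics(mk_trace(y3), integration_window_ms = 60)
  expect_equal(m3$rise_10_90, 0.8 * d, tolerance = 0.01)
})

test_that("charge is additive over noiseless components", {
  khz <- 20
  tt <- seq(0, 400, by = 1 / khz)
  y1 <- 80 * exp(-tt / 30)
  y2 <- 20 * exp(-tt / 150)
  q <- function(y) pracma::trapz(tt, y)
  expect_equal(q(y1 + y2), q(y1) + q(y2), tolerance = 1e-12)
})

test_that("weighted tau follows its closed form", {
  expect_equal(tau_weighted(3, 10, 1, 50), 20)
  expect_equal(tau_weighted(2, 12, 2, 48), (12 + 48) / 2)
})

test_that("bi-exponential fits recover noiseless components and flag collapse", {
  tt <- seq(0, 500, by = 0.05)
  y <- 3 * exp(-tt / 10) + 1 * exp(-tt / 50)
  fit <- fit_biexponential(tt, y)
  expect_equal(fit$tau1, 10, tolerance = 1e-3)
  expect_equal(fit$tau2, 50, tolerance = 1e-3)
  expect_equal(fit$tau_W, 20, tolerance = 1e-2)
  expect_false(fit$single_exponential)

  # equal time constants collapse to the flagged single-exponential form
  y2 <- 4 * exp(-tt / 30)
  fit2 <- fit_biexponential(tt, y2)
  expect_true(fit2$single_exponential)
  expect_equal(fit2$tau_W, 30, tolerance = 1e-3)

  expect_error(fit_biexponential(tt[1:10], y[1:10]),
               class = "fsiephys_insufficient_protocol")
})

test_that("tau_W is a convex combination of tau1 and tau2 on random fits", {
  set.seed(3)
  for (k in 1:100) {
    A <- runif(2, 0.2, 5); tau <- sort(runif(2, 2, 200))
    tt <- seq(0, 5 * tau[2], length.out = 400)
    y <- A[1] * exp(-tt / tau[1]) + A[2] * exp(-tt / tau[2]) +
      rnorm(400, 0, 0.01 * sum(A))
    fit <- tryCatch(fit_biexponential(tt, y), error = function(e) NULL)
    if (is.null(fit)) next
    expect_gte(fit$tau_W, min(fit$tau1, fit$tau2) - 1e-9)
    expect_lte(fit$tau_W, max(fit$tau1, fit$tau2) + 1e-9)
  }
})

test_that("block quantification: identity, scaling, and error cases", {
  pre <- list(peak_amplitude = 120, charge_Q = 9000, tau_W = 80)
  expect_equal(unlist(quantify_block(pre, pre)),
               c(pct_peak_reduction = 0, pct_Q_reduction = 0,
                 pct_change_tauW = 0))
  half <- list(peak_amplitude = 60, charge_Q = 4500, tau_W = 80)
  bl <- quantify_block(pre, half)
  expect_equal(bl$pct_peak_reduction, 50)
  expect_equal(bl$pct_Q_reduction, 50)
  expect_equal(bl$pct_change_tauW, 0)
  expect_error(quantify_block(list(peak_amplitude = 0, charge_Q = 1,
                                   tau_W = 1), half),
               class = "fsiephys_undefined_reference")
})

test_that("full selective GluN2B block leaves an AMPA-only synapse untouched", {
  p <- fsi_params("vehicle", noise_sigma = 0)
  base <- synaptic_params("vehicle", g_NMDA = 0, rate_sEPSC = 0,
                          rate_sIPSC = 0, tau_decay_NMDA_B = 109)
  blocked <- base; blocked$ifenprodil_block <- 1
  prot <- vc_protocol(-60, 3200, n_pulses = 6, pulse_period = 500)
  a <- simulate_voltage_clamp(p, base, prot, seed = 5)[[1]]
  b <- simulate_voltage_clamp(p, blocked, prot, seed = 5)[[1]]
  expect_identical(a$signal, b$signal)
})

test_that("isolation labels are validated against holding potential and tags", {
  p <- fsi_params("vehicle", noise_sigma = 0)
  iso <- isolate_nmda(synaptic_params("vehicle"))
  good <- simulate_voltage_clamp(p, iso$syn, vc_protocol(60, 500), seed = 1,
                                 tags = iso$tags, label = "NMDA")[[1]]
  expect_true(nmda_isolation_check(good))
  bad_hold <- simulate_voltage_clamp(p, iso$syn, vc_protocol(-60, 500),
                                     seed = 1, tags = iso$tags,
                                     label = "NMDA")[[1]]
  expect_error(nmda_isolation_check(bad_hold),
               class = "fsiephys_labeled_condition")
  no_tags <- simulate_voltage_clamp(p, iso$syn, vc_protocol(60, 500),
                                    seed = 1, label = "NMDA")[[1]]
  expect_error(nmda_isolation_check(no_tags),
               class = "fsiephys_labeled_condition")
  ampa <- simulate_voltage_clamp(p, synaptic_params("vehicle"),
                                 vc_protocol(-60, 500), seed = 1,
                                 label = "AMPA")[[1]]
  expect_true(nmda_isolation_check(ampa))
})
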