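# End-to-end pipeline: simulate cohorts -> extract intrinsic and synaptic
# features -> group comparison table.  Deterministic given the config seed.

#' Default pipeline configuration
#'
#' Study-scale defaults: 9 vehicle vs 13 mk801 cells, 600 ms steps, 1-5 pA
#' rheobase increments (1 pA used for the scan), 60 s spontaneous epochs per
#' condition, minimal stimulation with 20 pulses per evoked condition.
#'
#' @param ... Named overrides.
#' @return List of class `fsi_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_vehicle = 9L, n_mk801 = 13L,
    jitter_cv = 0.15, v_rest_sd = 1.5,
    dvdt_threshold = 10, floor_cv = 0.20,
    rheobase_start = 40, rheobase_increment = 1, rheobase_max = 600,
    latency_multiples = c(1.1, 1.25, 1.5, 1.75, 2.25, 2.5, 2.75, 3),
    threshold_offsets = seq(0, 300, by = 50),
    spont_duration_s = 60,
    n_evoked_pulses = 20,
    ifenprodil_block = 1.0,
    intrinsic = TRUE, synaptic = TRUE
  )
  modifyList(structure(cfg, class = "fsi_config"), list(...))
}

#' Read / write a pipeline configuration (YAML)
#' @param path YAML file.
#' @return An `fsi_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(default_config, cfg)
}

#' @rdname read_config
#' @param config An `fsi_config`.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Intrinsic-feature extraction for one simulated cell
#'
#' Runs the full current-clamp battery: passive steps (-300/-150/-100/-50
#' pA), rheobase scan, first-spike latency at rheobase, the latency-current
#' curve with regime classification, the threshold-dynamics series
#' (rheobase + 0..300 pA), and train features.  Single-spike waveform
#' features come from the first spike of the smallest-amplitude sweep that
#' elicits a continuous train (>= 5 spikes).
#'
#' @param params `fsi_params` for the cell.
#' @param cell_seed Integer seed for this cell's sweeps.
#' @param cfg `fsi_config`.
#' @return List: `features` (named numeric vector), `latency_curve`,
#'   `excluded` (logical), `qc` (list).
#' @export
extract_intrinsic <- function(params, cell_seed, cfg = default_config()) {
  feats <- c()
  qc <- list(flagged_crossings = 0L, excluded = FALSE, exclusion_reason = NULL)

  prot_pass <- step_protocol(c(-300, -150, -100, -50))
  ss_pass <- simulate_current_clamp(params, prot_pass, seed = cell_seed)
  pv <- measure_passive(ss_pass)
  feats["V_rest"] <- pv$V_rest
  feats["R_in"] <- pv$R_in
  feats["tau_m"] <- pv$tau_m
  feats["sag_Ih"] <- pv$sag_Ih

  provider <- make_cell_provider(params, seed = cell_seed)
  rb <- tryCatch(
    find_rheobase(provider, start_pA = cfg$rheobase_start,
                  increment = cfg$rheobase_increment,
                  max_pA = cfg$rheobase_max,
                  dvdt_threshold = cfg$dvdt_threshold),
    fsiephys_excluded_cell = function(e) e,
    fsiephys_rheobase_not_found = function(e) e)
  if (inherits(rb, "condition")) {
    qc$excluded <- TRUE
    qc$exclusion_reason <- conditionMessage(rb)
    return(list(features = feats, latency_curve = NULL, excluded = TRUE,
                qc = qc))
  }
  ith <- rb$I_th
  feats["I_th"] <- ith
  feats["first_spike_latency"] <-
    first_spike_latency(rb$latency_sweep, cfg$dvdt_threshold)
  sp0 <- detect_spikes(rb$latency_sweep, cfg$dvdt_threshold)
  feats["threshold_V"] <- sp0$threshold_V[1]
  qc$flagged_crossings <- qc$flagged_crossings + sum(!sp0$valid)

  prot_lat <- step_protocol(round(cfg$latency_multiples * ith))
  ss_lat <- simulate_current_clamp(params, prot_lat, seed = cell_seed + 7L)
  lc <- latency_current_curve(ss_lat, ith, floor_cv = cfg$floor_cv,
                              dvdt_threshold = cfg$dvdt_threshold)

  prot_thr <- step_protocol(ith + cfg$threshold_offsets)
  ss_thr <- simulate_current_clamp(params, prot_thr, seed = cell_seed + 13L)
  td <- threshold_dynamics(ss_thr, dvdt_threshold = cfg$dvdt_threshold)
  feats["threshold_slope"] <- td$slope

  # waveform features from the smallest amplitude giving a continuous train
  spikes_per <- vapply(ss_thr$sweeps, function(s)
    nrow(detect_spikes(s, cfg$dvdt_threshold)), numeric(1))
  k_train <- which(spikes_per >= 5)[1]
  if (!is.na(k_train)) {
    sw_train <- ss_thr[[k_train]]
    sp <- detect_spikes(sw_train, cfg$dvdt_threshold)
    qc$flagged_crossings <- qc$flagged_crossings + sum(!sp$valid)
    feats["half_width"] <- sp$half_width[1]
    feats["AHP_amplitude"] <- sp$AHP_amplitude[1]
    feats["t_AHP_peak"] <- sp$t_AHP_peak[1]
  }
  # train measures at the saturating (largest tested) amplitude
  tf_max <- train_features(ss_thr[[length(ss_thr)]], cfg$dvdt_threshold)
  feats["accommodation_ratio_ISI"] <- tf_max$accommodation_ratio_ISI
  feats["amp_ratio_1st_2nd"] <- tf_max$amp_ratio_1st_2nd
  feats["max_spike_freq"] <- tf_max$max_spike_freq
  feats["floor_present"] <- as.numeric(isTRUE(lc$floor_present))

  list(features = feats, latency_curve = lc, excluded = FALSE, qc = qc)
}

#' Synaptic-feature extraction for one simulated cell
#'
#' Spontaneous EPSC/IPSC frequencies under 2 mM and 0 mM Mg2+, the evoked
#' AMPA EPSC (held at -60 mV), the pharmacologically isolated NMDA EPSC
#' (+60 mV) before and after ifenprodil, and the block quantification.
#'
#' @param params,syn Cell parameters.
#' @param cell_seed Integer seed.
#' @param cfg `fsi_config`.
#' @return List: `features` (named numeric vector), `nmda_fit_pre`,
#'   `nmda_fit_post`, `block`.
#' @export
extract_synaptic <- function(params, syn, cell_seed, cfg = default_config()) {
  feats <- c()
  spont_ms <- cfg$spont_duration_s * 1000
  vc_noise <- params
  vc_noise$noise_sigma <- 3

  for (mg in c(2, 0)) {
    syn_mg <- syn; syn_mg$Mg_mM <- mg
    ss <- simulate_voltage_clamp(vc_noise, syn_mg,
                                 vc_protocol(-40, spont_ms),
                                 seed = cell_seed + 101L)
    ev <- detect_events(ss[[1]], "negative")
    feats[sprintf("sEPSC_freq_%gmM_Mg", mg)] <- ev$frequency
    ssi <- simulate_voltage_clamp(vc_noise, syn_mg, vc_protocol(10, spont_ms),
                                  seed = cell_seed + 103L)
    evi <- detect_events(ssi[[1]], "positive")
    feats[sprintf("sIPSC_freq_%gmM_Mg", mg)] <- evi$frequency
  }

  ev_prot <- function(holding)
    vc_protocol(holding, duration = cfg$n_evoked_pulses * 1000 + 200,
                n_pulses = cfg$n_evoked_pulses, pulse_period = 1000,
                first_pulse = 100)

  # evoked AMPA at -60 mV (NMDA largely Mg-blocked at this potential)
  ss_ampa <- simulate_voltage_clamp(vc_noise, syn, ev_prot(-60),
                                    seed = cell_seed + 211L, label = "AMPA")
  mt_a <- average_evoked(ss_ampa, window_ms = 200,
                         success_window_ms = c(1, 10), max_n = 10)
  fit_a <- evoked_fit(mt_a, integration_window_ms = 50)
  feats["AMPA_peak"] <- fit_a$peak_amplitude
  feats["AMPA_rise_10_90"] <- fit_a$rise_10_90
  feats["AMPA_tau_W"] <- fit_a$tau_W
  feats["AMPA_tau_fast"] <- fit_a$tau1
  feats["AMPA_failure_rate"] <- fit_a$failure_rate

  # isolated NMDA at +60 mV, pre and post ifenprodil
  iso <- isolate_nmda(syn)
  ss_n1 <- simulate_voltage_clamp(vc_noise, iso$syn, ev_prot(60),
                                  seed = cell_seed + 307L, tags = iso$tags,
                                  label = "NMDA")
  nmda_isolation_check(ss_n1[[1]])
  mt_n1 <- average_evoked(ss_n1, window_ms = 800,
                          success_window_ms = c(1, 100), max_n = 10)
  fit_n1 <- evoked_fit(mt_n1, integration_window_ms = 500)
  syn_post <- iso$syn; syn_post$ifenprodil_block <- cfg$ifenprodil_block
  ss_n2 <- simulate_voltage_clamp(vc_noise, syn_post, ev_prot(60),
                                  seed = cell_seed + 307L, tags = iso$tags,
                                  label = "NMDA")
  mt_n2 <- average_evoked(ss_n2, window_ms = 800,
                          success_window_ms = c(1, 100), max_n = 10)
  fit_n2 <- evoked_fit(mt_n2, integration_window_ms = 500)
  blk <- quantify_block(fit_n1, fit_n2)

  feats["NMDA_peak"] <- fit_n1$peak_amplitude
  feats["NMDA_rise_10_90"] <- fit_n1$rise_10_90
  feats["NMDA_tau_W"] <- fit_n1$tau_W
  feats["NMDA_failure_rate"] <- fit_n1$failure_rate
  feats["ifenprodil_pct_peak_reduction"] <- blk$pct_peak_reduction
  feats["ifenprodil_pct_Q_reduction"] <- blk$pct_Q_reduction
  feats["ifenprodil_pct_change_tauW"] <- blk$pct_change_tauW

  list(features = feats, nmda_fit_pre = fit_n1, nmda_fit_post = fit_n2,
       block = blk)
}

#' @noRd
feature_units <- function(name) {
  lut <- c(V_rest = "mV", R_in = "MOhm", tau_m = "ms", sag_Ih = "mV",
           I_th = "pA", first_spike_latency = "ms", threshold_V = "mV",
           threshold_slope = "mV/pA", half_width = "ms",
           AHP_amplitude = "mV", t_AHP_peak = "ms",
           accommodation_ratio_ISI = "ratio", amp_ratio_1st_2nd = "ratio",
           max_spike_freq = "Hz", floor_present = "bool",
           AMPA_peak = "pA", AMPA_rise_10_90 = "ms", AMPA_tau_W = "ms",
           AMPA_tau_fast = "ms",
           AMPA_failure_rate = "fraction", NMDA_peak = "pA",
           NMDA_rise_10_90 = "ms", NMDA_tau_W = "ms",
           NMDA_failure_rate = "fraction",
           ifenprodil_pct_peak_reduction = "%",
           ifenprodil_pct_Q_reduction = "%",
           ifenprodil_pct_change_tauW = "%")
  out <- lut[name]
  out[is.na(out)] <- if (length(out[is.na(out)]))
    ifelse(grepl("freq", name[is.na(out)]), "Hz", "unitless") else character(0)
  unname(out)
}

#' Run the full pipeline
#'
#' Simulates the cohort, extracts intrinsic and synaptic features per cell,
#' and writes the manifest, feature table, two-group comparison table, QC
#' report, config (with its checksum) and a log to `out_dir`.  Stages run in
#' order; a failing stage names itself and earlier outputs are preserved.
#'
#' @param config `fsi_config` (see [default_config()]) or a YAML path.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `features`, `group_table`, `cohort`, `qc`.
#' @export
run_all <- function(config = default_config(), out_dir = "fsiephys_run") {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = logf, append = TRUE)
  cat("", file = logf)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      fsi_error(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                "stage_failure"))
    log_line("stage %-12s %6.1f s", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  write_config(config, file.path(out_dir, "config.yaml"))
  md5 <- tools::md5sum(file.path(out_dir, "config.yaml"))
  writeLines(unname(md5), file.path(out_dir, "config.md5"))

  cohort <- stage("simulate", {
    co <- generate_cohort(c(config$n_vehicle, config$n_mk801),
                          seed = config$seed, jitter_cv = config$jitter_cv,
                          v_rest_sd = config$v_rest_sd)
    write_manifest(co$manifest, file.path(out_dir, "manifest.json"))
    co
  })

  rows <- list(); qc_all <- list()
  if (isTRUE(config$intrinsic)) {
    rows_i <- stage("intrinsic", lapply(cohort$cells, function(cell) {
      res <- extract_intrinsic(cell$params, cell$cell_seed, config)
      qc_all[[cell$cell_id]] <<- res$qc
      f <- res$features
      if (!length(f)) return(NULL)
      data.frame(cell_id = cell$cell_id, group_label = cell$group,
                 feature = names(f), value = unname(f),
                 units = feature_units(names(f)), n_sweeps = NA_integer_)
    }))
    rows <- c(rows, rows_i)
  }
  if (isTRUE(config$synaptic)) {
    rows_s <- stage("synaptic", lapply(cohort$cells, function(cell) {
      res <- extract_synaptic(cell$params, cell$syn, cell$cell_seed, config)
      f <- res$features
      data.frame(cell_id = cell$cell_id, group_label = cell$group,
                 feature = names(f), value = unname(f),
                 units = feature_units(names(f)), n_sweeps = NA_integer_)
    }))
    rows <- c(rows, rows_s)
  }
  features <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  features <- features[is.finite(features$value), ]
  stage("write_features",
        write_feature_table(features, file.path(out_dir, "features.tsv")))

  group_table <- stage("compare", {
    gt <- summarize_groups(features)
    write.table(gt, file.path(out_dir, "group_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    gt
  })

  jsonlite::write_json(qc_all, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       null = "null", digits = NA)
  log_line("done")
  invisible(list(features = features, group_table = group_table,
                 cohort = cohort, qc = qc_all))
}
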