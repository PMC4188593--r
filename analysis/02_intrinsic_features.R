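#!/usr/bin/env Rscript
# Stage 2: intrinsic/passive feature extraction for every cell of the
# simulated cohort: passive properties from hyperpolarizing steps, rheobase
# by the strict single-spike rule (1 pA increments, three trials), first-
# spike latency and its two stimulus regimes, phase-plot threshold dynamics,
# and spike-train measures.  Cells that never meet the single-spike rule are
# excluded, as in the recording protocol.

library(fsiephys)

seed <- 1L
cfg <- default_config(seed = seed)
out <- "results/02_intrinsic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- generate_cohort(c(cfg$n_vehicle, cfg$n_mk801), seed = seed,
                          jitter_cv = cfg$jitter_cv,
                          v_rest_sd = cfg$v_rest_sd)

rows <- list(); qc <- list()
for (cell in cohort$cells) {
  r <- extract_intrinsic(cell$params, cell$cell_seed, cfg)
  qc[[cell$cell_id]] <- r$qc
  if (r$excluded) {
    cat(sprintf("%-12s excluded (%s)\n", cell$cell_id,
                r$qc$exclusion_reason))
    next
  }
  f <- r$features
  cat(sprintf("%-12s I_th=%4.0f pA  R_in=%5.1f MOhm  latency=%6.1f ms  floor=%s\n",
              cell$cell_id, f["I_th"], f["R_in"], f["first_spike_latency"],
              f["floor_present"] == 1))
  rows[[cell$cell_id]] <- data.frame(
    cell_id = cell$cell_id, group_label = cell$group, feature = names(f),
    value = unname(f), units = fsiephys:::feature_units(names(f)),
    n_sweeps = NA_integer_)
}
feat <- do.call(rbind, rows)
feat <- feat[is.finite(feat$value), ]
write_feature_table(feat, file.path(out, "intrinsic_features.tsv"))
jsonlite::write_json(qc, file.path(out, "qc.json"), auto_unbox = TRUE,
                     pretty = TRUE, force = TRUE, digits = NA)
cat("wrote", file.path(out, "intrinsic_features.tsv"), "\n")
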