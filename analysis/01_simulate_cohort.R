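#!/usr/bin/env Rscript
# Stage 1: simulate the two-group FSI cohort (9 vehicle vs 13 mk801 cells)
# and write the manifest plus a small set of example sweeps.
#
# The mk801 phenotype differs from vehicle in a reduced Kv1-like D-current
# (25% of vehicle), a modestly reduced Kv3 conductance, a spike-activated
# adaptation current, and a GluN2B-enriched NMDA synapse with slower decay.
# Per-cell variability is multiplicative log-normal jitter on conductances.

library(fsiephys)

seed <- 1L
out <- "results/01_cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- generate_cohort(c(9, 13), seed = seed)
write_manifest(cohort$manifest, file.path(out, "manifest.json"))
cat("cohort:", nrow(cohort$manifest), "cells ->",
    file.path(out, "manifest.json"), "\n")

# example sweeps from the two preset cells: a rheobase-level step and a
# passive family, written in the package's text dialect
for (g in c("vehicle", "mk801")) {
  p <- fsi_params(g)
  ss <- simulate_current_clamp(p, step_protocol(c(-300, -100, 150, 300)),
                               seed = seed, cell_id = paste0(g, "_example"))
  write_sweeps(ss, file.path(out, paste0("sweeps_", g)))
}
cat("example sweeps written under", out, "\n")
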