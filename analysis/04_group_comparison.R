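#!/usr/bin/env Rscript
# Stage 4: aggregate per-cell features into the two-group comparison table
# (mean +/- SEM, n, two-tailed Student's t-test and one-way ANOVA, percent
# difference), mirroring the layout of a standard electrical-properties
# table.  Run stages 02 and 03 first.

library(fsiephys)

out <- "results/04_comparison"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

paths <- c("results/02_intrinsic/intrinsic_features.tsv",
           "results/03_synaptic/synaptic_features.tsv")
paths <- paths[file.exists(paths)]
stopifnot(length(paths) > 0)
feat <- do.call(rbind, lapply(paths, read_feature_table))

gt <- summarize_groups(feat)
write.table(gt, file.path(out, "group_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

show <- gt[, c("feature", "mean_vehicle", "sem_vehicle", "n_vehicle",
               "mean_mk801", "sem_mk801", "n_mk801", "p_ttest",
               "pct_difference")]
print(show, digits = 3, row.names = FALSE)
cat("\nwrote", file.path(out, "group_table.tsv"), "\n")
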