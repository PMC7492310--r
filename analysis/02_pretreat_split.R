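#!/usr/bin/env Rscript
# Stage 2: descriptor pretreatment and Kennard-Stone data division.
#
# Constant descriptors are dropped, then inter-correlated ones at the 0.7
# cutoff; the survivors are divided 70/30 by the deterministic maxmin
# algorithm. Writes the audit log and the membership table.

suppressMessages(library(qsarpipe))

tab <- read_descriptor_csv("results/descriptors.csv")
pic50 <- read_activity_csv("results/activity.csv")

pre <- pretreat(tab, cutoff = 0.7, variance_tol = 1e-8)
write_pretreat_report(pre$report, "results/pretreat_report.csv")
cat(sprintf("pretreatment: %d -> %d descriptors (%d constant, %d correlated)\n",
            ncol(tab), length(pre$report$survivors),
            length(pre$report$dropped_constant),
            nrow(pre$report$dropped_correlated)))

split <- ks_split(pre$table, train_fraction = 0.7)
ds <- apply_split(qsar_dataset(pre$table, pic50), split)
write.csv(data.frame(Name = names(ds$membership),
                     membership = unname(ds$membership)),
          "results/membership.csv", row.names = FALSE)
cat(sprintf("division: %d train / %d test (first picks: %s, %s)\n",
            length(split$train_ids), length(split$test_ids),
            split$selection_order[1], split$selection_order[2]))
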