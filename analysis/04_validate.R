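#!/usr/bin/env Rscript
# Stage 4: the validation suite.
#
# Internal metrics (R2, adjusted R2, leave-one-out Q2), external R2 on the
# held-out test set, per-descriptor diagnostics (VIF, mean effect, t/p/SE),
# the benchmark gate, Y-randomization with cRp2, and the leverage
# applicability domain. Writes all report tables.

suppressMessages(library(qsarpipe))

tab <- read_descriptor_csv("results/descriptors.csv")
pic50 <- read_activity_csv("results/activity.csv")
membership <- read.csv("results/membership.csv")
pre <- pretreat(tab)
ds <- qsar_dataset(pre$table, pic50,
                   setNames(membership$membership, membership$Name))
train <- subset_membership(ds, "train")
test <- subset_membership(ds, "test")
model <- read_model_json("results/model.json")

rep <- validation_report(model, train, test)
write.csv(rep$diagnostics, "results/diagnostics.csv", row.names = FALSE)
write.csv(as.data.frame(rep$verdict), "results/verdict.csv",
          row.names = FALSE)
cat(sprintf("validation: R2 = %.4f, R2adj = %.4f, Q2 = %.4f, R2ext = %.4f\n",
            rep$r2, rep$r2_adj, rep$q2_cv, rep$r2_ext))
cat(sprintf("benchmark gate: %s\n",
            if (attr(rep$verdict, "overall")) "PASS" else "FAIL"))
cat(sprintf("max VIF: %.3f; mean effects sum to %.6f\n",
            max(rep$diagnostics$vif), sum(rep$diagnostics$mean_effect)))

yr <- y_randomize(train$table, train$pic50, n_permutations = 10,
                  seed = 20260929, descriptors = model$descriptors)
write_yrand_csv(yr, "results/yrand.csv")
cat(sprintf("Y-randomization: mean random R2 = %.4f, cRp2 = %.4f\n",
            yr$avg_r2, yr$c_rp2))

ad <- williams(model, train, test)
con <- file("results/williams.csv", "w")
writeLines(sprintf("# h_star = %.10g, residual_band = %g",
                   attr(ad, "h_star"), attr(ad, "residual_band")), con)
write.csv(as.data.frame(ad), con, row.names = FALSE)
close(con)
cat(sprintf("applicability domain: h* = %.3f; %d of %d inside\n",
            attr(ad, "h_star"), sum(ad$inside_domain), nrow(ad)))
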