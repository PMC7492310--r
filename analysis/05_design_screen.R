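#!/usr/bin/env Rscript
# Stage 5: ligand-design screening with the bundled published model.
#
# Checks the published model's desk-scale statistics (ANOVA arithmetic,
# adjusted R2, cRp2) and screens the published designed-compound set
# against its template, reproducing the screening logic end to end.

suppressMessages(library(qsarpipe))

model <- hct116_model()
cat("bundled model:\n")
print(model)

# published regression statistics rebuilt from sums of squares
a <- anova_from_ss(2.349644479, 5, 0.8268128, 19)
r2 <- 1 - a$ss[2] / a$ss[3]
cat(sprintf("\nANOVA check: R2 = %.4f, MS_res = %.9f, F = %.5f\n",
            r2, a$ms[2], a$f[1]))
cat(sprintf("adjusted R2 at (n = 25, p = 5): %.4f\n",
            r2_adjusted(r2, 25, 5)))

ref <- yrand_reference()
orig <- ref[ref$Model == "Original", ]
rand_rs <- ref$R[ref$Model != "Original"]
cat(sprintf("Y-randomization record: mean random R = %.6f, cRp2 = %.6f\n",
            mean(rand_rs), c_rp2(orig$R, orig$R2, rand_rs)))

# screening the designed derivatives against the template
dc <- designed_compounds()
cand <- dc[dc$Name != "template", ]
template <- dc$pIC50[dc$Name == "template"]
cs <- candidate_set(cand$Name, cand$pIC50, template,
                    annotation = sprintf("R1=%s, R2=%s, R3=%s",
                                         cand$R1, cand$R2, cand$R3))
write.csv(as.data.frame(cs), "results/design_screen.csv",
          row.names = FALSE)
cat(sprintf("\n%d of %d designed compounds beat the template (pIC50 %.3f):\n",
            sum(cs$better_than_template), nrow(cs), template))
cat(" ", paste(sort(cs$id[cs$better_than_template]), collapse = ", "),
    "\n")
potent <- activity_threshold_filter(cs, ic50_max = 4.0)
cat(sprintf("below 4.0 uM predicted IC50: %s\n",
            paste(sort(potent$id), collapse = ", ")))
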