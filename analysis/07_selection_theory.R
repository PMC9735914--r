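#!/usr/bin/env Rscript
# Step 7 — Phenotypic selection theory: direct selection of DH lines vs
# indirect selection on their haploid progenitors.
#
# Indirect selection on haploids pays off only when rA(D,H) * h_H exceeds
# h_D. Applies the relative-efficiency calculator to the published
# per-trait correlation table and reports the verdict distribution, plus
# the hybrid-combination arithmetic that motivates preselection in the
# first place. Writes results/07_selection/.

library(dhpredict)

out <- "results/07_selection"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

t1 <- load_correlation_table()
eff <- selection_efficiency_table(t1)
write.csv(eff, file.path(out, "relative_efficiency.csv"), row.names = FALSE)

cat("Relative efficiency of indirect (haploid) vs direct (DH) selection:\n")
print(table(eff$verdict))
cat(sprintf("Median RE: %.2f (values < 1 favor direct selection)\n",
            median(eff$RE)))

best <- eff[which.max(eff$RE), ]
cat(sprintf("Most indirect-friendly trait: %s in %s (RE = %.2f)\n",
            best$trait, best$env, best$RE))

cat(sprintf("\n100 DH lines per heterotic pool -> %d candidate hybrids;\n",
            count_hybrid_combinations(100, 100)))
cat(sprintf("selecting the best 10%% per pool (i = %.2f) cuts that to %d.\n",
            selection_intensity(0.1), count_hybrid_combinations(10, 10)))
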