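#!/usr/bin/env Rscript
# Step 1 — Simulate the study population.
#
# Builds the synthetic biparental DH panel the rest of the analysis runs
# on: 187 lines on 10 chromosomes of 150 cM (132 markers each), 10% of
# lines derived after 3 extra selfing generations, plus the genetically
# identical haploid counterparts. Writes genotypes, the marker map and a
# demonstration multi-trait phenotype file under results/01_population/.

library(dhpredict)

out <- "results/01_population"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_lines = 187, seed = 2024)
sim <- simulate_biparental_dh(cfg)
hap <- derive_haploid_population(sim$geno)

cat(sprintf("Simulated %d DH lines x %d markers; %d lines with extra selfing.\n",
            nrow(sim$geno$dosages), ncol(sim$geno$dosages),
            sum(sim$selfed)))
cat(sprintf("All dosages homozygous: %s\n",
            all(sim$geno$dosages %in% c(0, 2))))
cat(sprintf("Mean crossovers per chromosome (F1-derived lines): %.2f (theory 1.5)\n",
            mean(sim$crossovers[!sim$selfed, ])))
cat(sprintf("Haploid genomes identical to their DH lines: %s\n",
            identical(hap$dosages, sim$geno$dosages)))

cfg_ph <- sim_config(n_lines = 187, n_traits = 3, n_envs = 2,
                     n_blocks = 2, seed = 2024)
K <- compute_grm(qc_filter(sim$geno)$geno)
ph <- simulate_phenotypes(K$matrix, cfg_ph)
write_simulated_study(sim$geno, ph$pheno, out)
write_grm_tsv(K, file.path(out, "grm.tsv"))
cat("Wrote genotypes, map, phenotypes and GRM to ", out, "\n", sep = "")
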