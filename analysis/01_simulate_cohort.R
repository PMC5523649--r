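#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# 50 cases / 30 controls with a TNFAIP3-like gene-region LD block
# (core/protective/risk haplotypes), an upstream regulatory block, a
# putative-functional SNP panel feeding the risk score, and a 40-variant
# trans region carrying one planted pQTL. Subject-level data for the real
# cohort are not deposited, so every downstream stage runs on this
# generator's output; the cohort files are plain VCF/TSV under
# results/cohort/.

suppressPackageStartupMessages(library(protqtl))

seed <- 20260920L
cfg <- default_sim_config(seed = seed)
cohort <- simulate_cohort(cfg)
print(cohort)

files <- write_cohort(cohort, "results/cohort")
cat("wrote:", paste(basename(files), collapse = ", "), "\n")

cat(sprintf("planted pQTL: %s, beta = %.3f per alt allele (log scale)\n",
            cfg$planted_pqtl$variant, cfg$planted_pqtl$beta))
cat(sprintf("age %0.f +/- %0.f; %0.f%% male\n",
            mean(cohort$subjects$age), sd(cohort$subjects$age),
            100 * mean(cohort$subjects$sex == "male")))
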