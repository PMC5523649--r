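#!/usr/bin/env Rscript
# Stage 5: association scans.
#
# Additive logistic regression of case/control status on each variant
# (age/sex adjusted), then the pQTL linear scan of the transformed phenotype
# in cases, controls and the combined group, with the top hits of the
# combined scan verified by the permutation routine under the same model.

suppressPackageStartupMessages(library(protqtl))
co <- read_cohort("results/cohort")
hw <- hwe_filter(co$genotypes, co$subjects)
pheno <- read.delim("results/phenotypes_transformed.tsv")
y <- setNames(pheno$transformed, pheno$subject_id)

lg <- logistic_scan(hw$kept, co$subjects)
lg <- lg[order(lg$p_asymptotic), ]
cat(sprintf("logistic scan: %d variants, %d estimable, top p = %.3g (%s)\n",
            nrow(lg), sum(lg$estimable), lg$p_asymptotic[1], lg$variant_id[1]))
write.table(lg, "results/logistic_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (st in c("all", "case", "control")) {
  sc <- pqtl_scan(hw$kept, y, co$subjects, stratum = st)
  if (st == "all")
    sc <- permute_top_hits(sc, hw$kept, y, co$subjects, stratum = st,
                           top_k = 30L, n_perm = 20000L, seed = 5L)
  sc <- sc[order(sc$p_asymptotic), ]
  cat(sprintf("pQTL scan [%s]: top hit %s, asymptotic p = %.3g%s\n",
              st, sc$variant_id[1], sc$p_asymptotic[1],
              if ("p_permuted" %in% names(sc) && !is.na(sc$p_permuted[1]))
                sprintf(", permuted p = %.3g", sc$p_permuted[1]) else ""))
  write.table(sc, sprintf("results/pqtl_%s.tsv", st), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
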