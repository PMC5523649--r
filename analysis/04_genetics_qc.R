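#!/usr/bin/env Rscript
# Stage 4: genotype QC and variant burdens.
#
# Exact Hardy-Weinberg testing within cases and within controls (variants
# with p < 1e-5 in either stratum are excluded), per-subject burdens of
# upstream and gene-region variants, and the unweighted genetic risk score
# over putative functional variants, compared between statuses by the
# permutation T test and a Kolmogorov-Smirnov distribution test.

suppressPackageStartupMessages(library(protqtl))
co <- read_cohort("results/cohort")

hw <- hwe_filter(co$genotypes, co$subjects, threshold = 1e-5)
cat(sprintf("HWE QC: %d of %d variants excluded at p < 1e-5\n",
            hw$n_excluded, ncol(co$genotypes$codes)))
write.table(hw$results, "results/hwe_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

grs <- genetic_risk_score(hw$kept)
upstream <- burden_by_region(hw$kept,
                             function(v) v$region_class == "upstream_regulatory")
grp <- co$subjects$group[match(names(grs), co$subjects$id)]
cat(sprintf("risk score: cases %.2f (SD %.2f), controls %.2f (SD %.2f)\n",
            mean(grs[grp == "case"]), sd(grs[grp == "case"]),
            mean(grs[grp == "control"]), sd(grs[grp == "control"])))

pt <- permuted_mean_test(grs, grp, n_perm = 20000L, seed = 4L)
ks <- ks_two_sample(grs[grp == "case"], grs[grp == "control"])
cat(sprintf("status difference: permuted p = %.3f, KS p = %.3f\n",
            pt$p_perm, ks$p))

write.table(data.frame(subject_id = names(grs), group = grp,
                       risk_score = as.integer(grs),
                       upstream_burden = as.integer(upstream)),
            "results/risk_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
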