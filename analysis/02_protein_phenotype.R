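#!/usr/bin/env Rscript
# Stage 2: protein phenotype analysis.
#
# Normalizes the analyte to total lysate protein, checks normality
# (Shapiro-Wilk), Box-Cox transforms, compares cases and controls with the
# permutation T test (Mann-Whitney as cross-check), looks for expression
# subgroups among cases by k-means/UPGMA, and flags cases at or below the
# control 25th percentile as low expressers.

suppressPackageStartupMessages(library(protqtl))
dir.create("results", showWarnings = FALSE)
co <- read_cohort("results/cohort")

ph <- co$phenotypes
normalized <- normalize_phenotype(ph$raw, ph$total_protein, ph$subject_id)
sw <- shapiro_wilk(normalized)
cat(sprintf("Shapiro-Wilk on normalized ratios: W = %.3f, p = %.2g%s\n",
            sw$W, sw$p,
            if (sw$p < 0.05) " -> departs from Gaussian, transforming" else ""))

off <- offset_for_boxcox(normalized)
fit <- boxcox_fit(normalized + off)
transformed <- boxcox_transform(normalized + off, fit$lambda)
cat(sprintf("Box-Cox lambda = %.2f (offset %.3g)\n", fit$lambda, off))

grp <- co$subjects$group[match(ph$subject_id, co$subjects$id)]
pt <- permuted_mean_test(transformed, grp, n_perm = 20000L, seed = 2L)
print(pt)

write.table(data.frame(subject_id = ph$subject_id, normalized = normalized,
                       lambda = fit$lambda, transformed = transformed,
                       group = grp),
            "results/phenotypes_transformed.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cases <- ph$subject_id[grp == "case"]
ctrls <- ph$subject_id[grp == "control"]
names(normalized) <- ph$subject_id
km <- cluster_phenotype(normalized[cases], "kmeans", k_range = 1:4, seed = 3L)
cat("k-means WSS by k:", paste(sprintf("%.0f", km$wss), collapse = ", "), "\n")
up <- cluster_phenotype(normalized[cases], "upgma", k_range = 2:4)

flags <- low_expresser_flags(normalized[ctrls], normalized[cases])
cat(sprintf("low-expresser threshold (control 25th pct): %.1f; %d/%d cases low\n",
            attr(flags, "threshold"), sum(flags), length(flags)))
write.table(data.frame(subject_id = cases,
                       kmeans_k2 = km$labels[["2"]],
                       upgma_k2 = up$labels[["2"]],
                       low_expresser = as.logical(flags)),
            "results/case_subgroups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
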