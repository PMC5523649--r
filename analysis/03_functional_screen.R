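#!/usr/bin/env Rscript
# Stage 3: functional correlation screen.
#
# Spearman correlations between the normalized protein level and every
# (stimulus, analyte) signaling/cytokine readout, plus fold-induction
# (stimulated / untreated) variants, with a Bonferroni experiment-wise flag
# across all tests in the screen.

suppressPackageStartupMessages(library(protqtl))
co <- read_cohort("results/cohort")

ph <- co$phenotypes
screen <- correlation_screen(
  data.frame(subject_id = ph$subject_id,
             value = normalize_phenotype(ph$raw, ph$total_protein)),
  co$readouts, alpha = 0.05)

cat(sprintf("%d correlation tests, %d experiment-wise significant\n",
            attr(screen, "n_tests"), sum(screen$significant_experimentwise)))
print(head(screen, 10), digits = 3)

write.table(screen, "results/correlation_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
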