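#!/usr/bin/env Rscript
# Stage 7: single-command reproduction.
#
# Runs the whole analysis (stages 1-6) through the orchestrator with one
# master seed, then renders the plain result figures. Output under
# results/pipeline/ is byte-identical across re-runs with the same seed.

suppressPackageStartupMessages(library(protqtl))

cfg <- pipeline_config(out_dir = "results/pipeline",
                       simulation = default_sim_config(),
                       n_perm = 20000L, top_k = 30L,
                       master_seed = 20260920L)
report <- run_pipeline(cfg)
for (nm in names(report$stages)) {
  st <- report$stages[[nm]]
  cat(sprintf("%-20s %s\n", nm,
              if (!is.null(st$error)) paste("ERROR:", st$error)
              else if (isTRUE(st$skipped)) "skipped" else "ok"))
}
figs <- render_plots("results/pipeline")
cat("figures:", paste(basename(figs), collapse = ", "), "\n")
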