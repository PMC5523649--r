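# End-to-end orchestration: simulate-or-read -> normalize/transform ->
# case/control comparison -> correlation screen -> HWE QC -> burden and risk
# score -> association scans with top-hit permutation -> haplotype phasing
# and variant groups. Every stochastic stage gets its own seed derived from
# the master seed by a fixed offset, recorded in the run report.

#' Build and validate a pipeline configuration
#'
#' @param out_dir output directory for result tables and the run report.
#' @param simulation a \code{sim_config} to generate the cohort (its seed is
#'   overridden by the master seed fan-out), or \code{NULL} when reading.
#' @param input_dir directory with cohort files (see [read_cohort()]);
#'   exactly one of \code{simulation}/\code{input_dir} must be given.
#' @param analyte phenotype analyte of interest (default "TNFAIP3").
#' @param haplotype_gene gene whose variants are phased (default "TNFAIP3").
#' @param n_perm permutations for every permutation test (default 1e6, the
#'   stable-small-p setting; smaller values trade precision for speed as
#'   quantified by [mc_pvalue_ci()]).
#' @param alpha experiment-wise significance level (default 0.05).
#' @param hwe_threshold HWE exclusion threshold (default 1e-5).
#' @param top_k number of top pQTL hits to verify by permutation
#'   (default 30).
#' @param pqtl_verify_stratum stratum whose scan is permutation-verified.
#' @param gibbs_iter,gibbs_burn Gibbs sampler budget (default 2000 / 500).
#' @param master_seed integer master seed; stage seeds are
#'   \code{master_seed + fixed offsets}.
#' @return validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir, simulation = NULL, input_dir = NULL,
                            analyte = "TNFAIP3", haplotype_gene = "TNFAIP3",
                            n_perm = 1e6, alpha = 0.05,
                            hwe_threshold = 1e-5, top_k = 30L,
                            pqtl_verify_stratum = "all",
                            gibbs_iter = 2000L, gibbs_burn = 500L,
                            master_seed = 1L) {
  if (is.null(simulation) == is.null(input_dir))
    stop("provide exactly one of 'simulation' or 'input_dir'")
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (hwe_threshold <= 0 || hwe_threshold >= 1)
    stop("hwe_threshold must be in (0, 1)")
  structure(list(out_dir = out_dir, simulation = simulation,
                 input_dir = input_dir, analyte = analyte,
                 haplotype_gene = haplotype_gene, n_perm = as.integer(n_perm),
                 alpha = alpha, hwe_threshold = hwe_threshold,
                 top_k = as.integer(top_k),
                 pqtl_verify_stratum = pqtl_verify_stratum,
                 gibbs_iter = as.integer(gibbs_iter),
                 gibbs_burn = as.integer(gibbs_burn),
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing one TSV per result table under
#' \code{config$out_dir} plus a machine-readable \code{report.json} and a
#' human-readable \code{report.txt}. A stage failure is recorded in the
#' report and downstream stages are skipped. Identical config and master
#' seed produce byte-identical numeric outputs.
#'
#' @param config a \code{pipeline_config}.
#' @return invisibly, the run report (list of per-stage records).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- config$master_seed + c(data = 1L, compare = 2L, cluster = 3L,
                                  scans = 4L, phase = 5L, groups = 6L,
                                  risk = 7L)
  report <- list(created = "run_pipeline",
                 parameters = config[setdiff(names(config), "simulation")],
                 seeds = as.list(seeds), stages = list())
  failed <- FALSE
  add_stage <- function(name, outputs = character(0), ...) {
    report$stages[[name]] <<- c(list(outputs = outputs), list(...))
  }
  run_stage <- function(name, fun) {
    if (failed) {
      report$stages[[name]] <<- list(skipped = TRUE)
      return(invisible(NULL))
    }
    tryCatch(fun(), error = function(e) {
      failed <<- TRUE
      report$stages[[name]] <<- list(error = conditionMessage(e))
      NULL
    })
  }
  env <- new.env()

  run_stage("data", function() {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      sim$seed <- seeds[["data"]]
      env$cohort <- simulate_cohort(sim)
      write_cohort(env$cohort, file.path(out, "cohort"))
      add_stage("data", outputs = file.path(out, "cohort"),
                source = "simulated", seed = seeds[["data"]],
                n_subjects = nrow(env$cohort$subjects))
    } else {
      env$cohort <- read_cohort(config$input_dir)
      add_stage("data", source = config$input_dir,
                n_subjects = nrow(env$cohort$subjects))
    }
  })

  run_stage("phenotype", function() {
    co <- env$cohort
    ph <- co$phenotypes[co$phenotypes$analyte == config$analyte, ]
    if (!nrow(ph)) stop("no phenotype rows for analyte ", config$analyte)
    normalized <- normalize_phenotype(ph$raw, ph$total_protein, ph$subject_id)
    sw <- shapiro_wilk(normalized)
    off <- offset_for_boxcox(normalized)
    fit <- boxcox_fit(normalized + off)
    transformed <- boxcox_transform(normalized + off, fit$lambda)
    tab <- data.frame(subject_id = ph$subject_id, raw = ph$raw,
                      total_protein = ph$total_protein,
                      normalized = normalized, offset = off,
                      lambda = fit$lambda, transformed = transformed,
                      stringsAsFactors = FALSE)
    f <- file.path(out, "phenotypes_transformed.tsv")
    .write_tsv(tab, f)
    env$pheno <- stats::setNames(transformed, ph$subject_id)
    env$pheno_norm <- stats::setNames(normalized, ph$subject_id)
    add_stage("phenotype", outputs = f, shapiro_W = sw$W, shapiro_p = sw$p,
              boxcox_lambda = fit$lambda, boxcox_offset = off)
  })

  run_stage("group_comparison", function() {
    co <- env$cohort
    grp <- co$subjects$group[match(names(env$pheno), co$subjects$id)]
    pt <- permuted_mean_test(env$pheno, grp, n_perm = config$n_perm,
                             seed = seeds[["compare"]])
    tab <- data.frame(analyte = config$analyte,
                      mean_case = pt$means[["case"]],
                      mean_control = pt$means[["control"]],
                      observed_T = pt$observed_stat, n_perm = pt$n_perm,
                      p_perm = pt$p_perm, p_perm_add1 = pt$p_perm_add1,
                      ci_lo = pt$ci95[1], ci_hi = pt$ci95[2],
                      p_mann_whitney = pt$p_mann_whitney)
    f <- file.path(out, "group_comparison.tsv")
    .write_tsv(tab, f)

    cases <- co$subjects$id[co$subjects$group == "case"]
    ctrls <- co$subjects$id[co$subjects$group == "control"]
    km <- cluster_phenotype(env$pheno_norm[cases], "kmeans", k_range = 2:3,
                            seed = seeds[["cluster"]])
    up <- cluster_phenotype(env$pheno_norm[cases], "upgma", k_range = 2:3)
    cl <- data.frame(subject_id = cases,
                     kmeans_k2 = km$labels[["2"]], kmeans_k3 = km$labels[["3"]],
                     upgma_k2 = up$labels[["2"]], upgma_k3 = up$labels[["3"]])
    f2 <- file.path(out, "clusters.tsv")
    .write_tsv(cl, f2)
    flags <- low_expresser_flags(env$pheno_norm[ctrls], env$pheno_norm[cases])
    f3 <- file.path(out, "low_expressers.tsv")
    .write_tsv(data.frame(subject_id = cases, low_expresser = as.logical(flags)),
               f3)
    add_stage("group_comparison", outputs = c(f, f2, f3),
              seed = seeds[["compare"]], p_perm = pt$p_perm,
              low_expresser_threshold = attr(flags, "threshold"))
  })

  run_stage("correlation_screen", function() {
    co <- env$cohort
    if (is.null(co$readouts) || !nrow(co$readouts)) {
      add_stage("correlation_screen", note = "no readouts")
      return()
    }
    scr <- correlation_screen(
      data.frame(subject_id = names(env$pheno_norm),
                 value = unname(env$pheno_norm)),
      co$readouts, alpha = config$alpha)
    f <- file.path(out, "correlation_screen.tsv")
    .write_tsv(scr, f)
    add_stage("correlation_screen", outputs = f,
              n_tests = attr(scr, "n_tests"),
              n_significant = sum(scr$significant_experimentwise))
  })

  run_stage("genetics_qc", function() {
    co <- env$cohort
    hw <- hwe_filter(co$genotypes, co$subjects,
                     threshold = config$hwe_threshold)
    f <- file.path(out, "hwe_report.tsv")
    .write_tsv(hw$results, f)
    env$geno <- hw$kept

    grs <- genetic_risk_score(hw$kept, subjects = co$subjects)
    upstream <- burden_by_region(hw$kept, function(v)
      v$region_class == "upstream_regulatory")
    gene_reg <- burden_by_region(hw$kept, function(v)
      !is.na(v$gene) & v$gene == config$haplotype_gene)
    tab <- data.frame(subject_id = names(grs),
                      group = co$subjects$group[match(names(grs),
                                                      co$subjects$id)],
                      risk_score = as.integer(grs),
                      upstream_burden = as.integer(upstream),
                      gene_burden = as.integer(gene_reg))
    f2 <- file.path(out, "risk_scores.tsv")
    .write_tsv(tab, f2)
    pt <- permuted_mean_test(tab$risk_score, tab$group,
                             n_perm = config$n_perm, seed = seeds[["risk"]])
    ks <- ks_two_sample(tab$risk_score[tab$group == "case"],
                        tab$risk_score[tab$group == "control"])
    tests <- data.frame(
      mean_case = mean(tab$risk_score[tab$group == "case"]),
      sd_case = stats::sd(tab$risk_score[tab$group == "case"]),
      mean_control = mean(tab$risk_score[tab$group == "control"]),
      sd_control = stats::sd(tab$risk_score[tab$group == "control"]),
      p_perm = pt$p_perm, ks_D = ks$D, ks_p = ks$p)
    f3 <- file.path(out, "risk_score_tests.tsv")
    .write_tsv(tests, f3)
    add_stage("genetics_qc", outputs = c(f, f2, f3),
              seed = seeds[["risk"]], n_excluded = hw$n_excluded)
  })

  run_stage("association", function() {
    co <- env$cohort
    pos <- env$geno$variants[, c("id", "chrom", "pos", "gene")]
    decorate <- function(res) {
      res <- merge(res, pos, by.x = "variant_id", by.y = "id", sort = FALSE)
      res[order(res$p_asymptotic), ]
    }
    lg <- decorate(logistic_scan(env$geno, co$subjects))
    f <- file.path(out, "logistic_scan.tsv")
    .write_tsv(lg, f)
    files <- f
    for (st in c("all", "case", "control")) {
      sc <- pqtl_scan(env$geno, env$pheno, co$subjects, stratum = st)
      if (st == config$pqtl_verify_stratum)
        sc <- permute_top_hits(sc, env$geno, env$pheno, co$subjects,
                               stratum = st, top_k = config$top_k,
                               n_perm = config$n_perm,
                               seed = seeds[["scans"]])
      fs <- file.path(out, paste0("pqtl_", st, ".tsv"))
      .write_tsv(decorate(sc), fs)
      files <- c(files, fs)
    }
    add_stage("association", outputs = files, seed = seeds[["scans"]])
  })

  run_stage("haplotypes", function() {
    co <- env$cohort
    sel <- which(!is.na(env$geno$variants$gene) &
                   env$geno$variants$gene == config$haplotype_gene &
                   env$geno$variants$region_class != "upstream_regulatory")
    if (!length(sel)) {
      add_stage("haplotypes", note = "no gene-region variants after QC")
      return()
    }
    sel <- utils::head(sel, 25L)
    region <- subset_variants(env$geno, sel)
    phz <- gibbs_phase(region, n_iter = config$gibbs_iter,
                       burn_in = config$gibbs_burn, seed = seeds[["phase"]])
    f1 <- file.path(out, "haplotype_phases.tsv")
    .write_tsv(phz$phases, f1)
    f2 <- file.path(out, "haplotype_freqs.tsv")
    .write_tsv(phz$frequencies, f2)

    gdefs <- if (!is.null(config$simulation)) {
      lapply(config$simulation$group_defs, function(gd)
        intersect(gd$variants, region$variants$id))
    } else {
      list()   # group definitions must come with annotations otherwise
    }
    files <- c(f1, f2)
    if (length(gdefs)) {
      labels <- assign_groups(region, gdefs)
      f3 <- file.path(out, "variant_groups.tsv")
      .write_tsv(labels, f3)
      cmp <- group_phenotype_comparison(labels, env$pheno,
                                        n_perm = config$n_perm,
                                        seed = seeds[["groups"]])
      f4 <- file.path(out, "variant_group_comparison.tsv")
      .write_tsv(cmp, f4)
      files <- c(files, f3, f4)
    }

    # trend of the reference (all-0) haplotype dosage across status
    ref <- strrep("0", ncol(region$codes))
    copies <- (phz$phases$hap1 == ref) + (phz$phases$hap2 == ref)
    grp <- co$subjects$group[match(phz$phases$subject_id, co$subjects$id)]
    tbl <- rbind(case = table(factor(copies[grp == "case"], levels = 0:2)),
                 control = table(factor(copies[grp == "control"],
                                        levels = 0:2)))
    ca <- cochran_armitage(tbl)
    f5 <- file.path(out, "trend_test.tsv")
    .write_tsv(data.frame(haplotype = ref, Z = ca$Z, p = ca$p), f5)
    add_stage("haplotypes", outputs = c(files, f5), seed = seeds[["phase"]],
              trend_p = ca$p)
  })

  report$failed <- failed
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  txt <- c("protqtl pipeline report",
           paste0("master seed: ", config$master_seed),
           paste0("n_perm: ", config$n_perm),
           "",
           vapply(names(report$stages), function(nm) {
             st <- report$stages[[nm]]
             status <- if (!is.null(st$error)) paste("ERROR:", st$error)
               else if (isTRUE(st$skipped)) "skipped" else "ok"
             paste0(nm, ": ", status)
           }, character(1)))
  writeLines(txt, file.path(out, "report.txt"))
  invisible(report)
}

#' Render plain result plots from pipeline output tables
#'
#' Regional association scatter (-log10 p against position, planted/top
#' region), phenotype strip chart by variant group, and burden histograms by
#' status. Empty or missing inputs produce no figures and a warning.
#'
#' @param out_dir pipeline output directory.
#' @param fig_dir where to write PNG figures (default
#'   \code{file.path(out_dir, "figures")}).
#' @return invisibly, the figure files written.
#' @export
render_plots <- function(out_dir, fig_dir = file.path(out_dir, "figures")) {
  written <- character(0)
  scan_path <- file.path(out_dir, "pqtl_all.tsv")
  grp_path <- file.path(out_dir, "variant_groups.tsv")
  ph_path <- file.path(out_dir, "phenotypes_transformed.tsv")
  risk_path <- file.path(out_dir, "risk_scores.tsv")
  if (!file.exists(scan_path) && !file.exists(risk_path)) {
    warning("no result tables found in ", out_dir, "; nothing to plot")
    return(invisible(written))
  }
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

  if (file.exists(scan_path)) {
    sc <- .read_tsv(scan_path)
    sc <- sc[!is.na(sc$p_asymptotic) & !is.na(sc$pos), ]
    if (nrow(sc)) {
      top_chrom <- sc$chrom[which.min(sc$p_asymptotic)]
      reg <- sc[sc$chrom == top_chrom, ]
      f <- file.path(fig_dir, "regional_association.png")
      grDevices::png(f, width = 900, height = 500)
      graphics::plot(reg$pos / 1e6, -log10(reg$p_asymptotic),
                     pch = 19, col = "steelblue",
                     xlab = paste0("position on ", top_chrom, " (Mb)"),
                     ylab = expression(-log[10](p)),
                     main = "pQTL scan (combined group)")
      graphics::abline(h = -log10(0.05 / nrow(sc)), lty = 2, col = "grey40")
      grDevices::dev.off()
      written <- c(written, f)
    }
  }
  if (file.exists(grp_path) && file.exists(ph_path)) {
    gl <- .read_tsv(grp_path); ph <- .read_tsv(ph_path)
    d <- merge(gl, ph, by = "subject_id")
    d <- d[d$label != "excluded_conflict", ]
    if (nrow(d)) {
      f <- file.path(fig_dir, "phenotype_by_group.png")
      grDevices::png(f, width = 700, height = 500)
      graphics::stripchart(transformed ~ factor(label), data = d,
                           vertical = TRUE, method = "jitter", pch = 19,
                           col = "darkorange3",
                           ylab = "transformed phenotype",
                           main = "phenotype by variant group")
      meds <- tapply(d$transformed, d$label, stats::median)
      graphics::segments(seq_along(meds) - 0.2, meds,
                         seq_along(meds) + 0.2, meds, col = "red", lwd = 2)
      grDevices::dev.off()
      written <- c(written, f)
    }
  }
  if (file.exists(risk_path)) {
    rs <- .read_tsv(risk_path)
    if (nrow(rs)) {
      f <- file.path(fig_dir, "burden_histogram.png")
      grDevices::png(f, width = 700, height = 500)
      brk <- seq(-0.5, max(rs$risk_score) + 0.5, by = 1)
      h_case <- graphics::hist(rs$risk_score[rs$group == "case"],
                               breaks = brk, plot = FALSE)
      h_ctrl <- graphics::hist(rs$risk_score[rs$group == "control"],
                               breaks = brk, plot = FALSE)
      graphics::barplot(rbind(case = h_case$counts, control = h_ctrl$counts),
                        beside = TRUE, names.arg = h_case$mids,
                        col = c("firebrick", "steelblue"),
                        legend.text = TRUE, xlab = "risk score",
                        ylab = "subjects", main = "variant burden by status")
      grDevices::dev.off()
      written <- c(written, f)
    }
  }
  if (!length(written)) warning("result tables were empty; no figures drawn")
  invisible(written)
}
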