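# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes for a small
# case/control cohort with a targeted sequencing panel: haplotype-block
# genotypes containing core/protective/risk variant sets, a right-skewed
# (log-normal) normalized protein phenotype lower on average in cases,
# additive genetic effects planted on the log scale, and functional readouts
# tied to the latent phenotype through a Gaussian copula on ranks so that a
# target Spearman correlation can be dialled in.

#' Define an LD block by its haplotype pool
#'
#' @param haplotypes character vector of equal-length 0/1 strings, one per
#'   pooled haplotype.
#' @param freqs haplotype frequencies, summing to 1.
#' @param name block name; variant ids are \code{<name>_<i>}.
#' @param chrom,start,spacing variant coordinates: positions are
#'   \code{start + (i-1) * spacing}.
#' @param gene gene label for all variants in the block.
#' @param region_class per-variant region class (recycled).
#' @param functional per-variant putative-functional flag (recycled).
#' @return a block specification list.
#' @export
hap_block <- function(haplotypes, freqs, name, chrom = "chr6",
                      start = 1000L, spacing = 500L, gene = name,
                      region_class = "intronic", functional = FALSE) {
  L <- unique(nchar(haplotypes))
  if (length(L) != 1) stop("haplotypes must have equal length in block ", name)
  pool <- do.call(rbind, lapply(strsplit(haplotypes, ""), as.integer))
  if (!all(pool %in% 0:1)) stop("haplotypes must be 0/1 strings in block ", name)
  list(name = name, pool = pool, freqs = freqs, chrom = chrom,
       start = as.integer(start), spacing = as.integer(spacing),
       gene = gene,
       region_class = rep_len(region_class, L),
       functional = rep_len(functional, L),
       n_variants = L)
}

#' Define a single independent SNP as a one-site block
#'
#' @param maf alternate-allele frequency.
#' @inheritParams hap_block
#' @export
snp_block <- function(maf, name, chrom = "chr1", start = 1000L,
                      gene = name, region_class = "intergenic",
                      functional = FALSE) {
  hap_block(c("0", "1"), c(1 - maf, maf), name = name, chrom = chrom,
            start = start, gene = gene, region_class = region_class,
            functional = functional)
}

#' Build and validate a simulation configuration
#'
#' @param n_cases,n_controls cohort sizes (each at least 2).
#' @param variant_blocks list of blocks from [hap_block()]/[snp_block()].
#' @param group_defs named list (\code{core}, \code{protective},
#'   \code{risk}) of lists with \code{variants} (ids) and \code{shift}
#'   (additive effect on the log phenotype scale for carriers of the set).
#' @param planted_pqtl \code{NULL}, or list with \code{variant} (id) and
#'   \code{beta} (additive per-allele effect on the log phenotype scale).
#' @param phenotype list with \code{analyte}, per-status \code{case} /
#'   \code{control} vectors \code{c(log_mean, log_sd)} of the normalized
#'   ratio, and \code{total_protein = c(log_mean, log_sd)}.
#' @param readout_specs data.frame with \code{stimulus}, \code{analyte},
#'   \code{rho} (target Spearman correlation with the latent phenotype,
#'   \code{|rho| < 1}), \code{log_mean}, \code{log_sd}.
#' @param covariates list with \code{age_mean}, \code{age_sd},
#'   \code{age_min}, \code{prop_male}.
#' @param missing_rate uniform genotype missingness rate in \eqn{[0, 1)}.
#' @param seed integer master seed; identical configs and seeds produce
#'   bit-identical datasets.
#' @return validated object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_cases, n_controls, variant_blocks,
                       group_defs = list(), planted_pqtl = NULL,
                       phenotype, readout_specs = NULL,
                       covariates = list(age_mean = 52, age_sd = 12,
                                         age_min = 18, prop_male = 0.49),
                       missing_rate = 0, seed = 1L) {
  cfg <- structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    variant_blocks = variant_blocks, group_defs = group_defs,
    planted_pqtl = planted_pqtl, phenotype = phenotype,
    readout_specs = readout_specs, covariates = covariates,
    missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config object to validate.
#' @export
validate_sim_config <- function(config) {
  fail <- function(field, msg) stop("invalid config field '", field, "': ",
                                    msg, call. = FALSE)
  if (is.na(config$n_cases) || config$n_cases < 2)
    fail("n_cases", "must be at least 2")
  if (is.na(config$n_controls) || config$n_controls < 2)
    fail("n_controls", "must be at least 2")
  ids <- character(0)
  for (i in seq_along(config$variant_blocks)) {
    b <- config$variant_blocks[[i]]
    if (abs(sum(b$freqs) - 1) > 1e-9)
      fail(sprintf("variant_blocks[[%d]]$freqs", i),
           sprintf("frequencies sum to %.10f, not 1", sum(b$freqs)))
    if (length(b$freqs) != nrow(b$pool))
      fail(sprintf("variant_blocks[[%d]]", i),
           "one frequency per pooled haplotype required")
    if (any(b$freqs < 0))
      fail(sprintf("variant_blocks[[%d]]$freqs", i), "negative frequency")
    ids <- c(ids, paste0(b$name, "_", seq_len(b$n_variants)))
  }
  if (anyDuplicated(ids)) fail("variant_blocks", "duplicated variant ids")
  for (nm in names(config$group_defs)) {
    gd <- config$group_defs[[nm]]
    bad <- setdiff(gd$variants, ids)
    if (length(bad))
      fail(paste0("group_defs$", nm), paste("unknown variant id(s):",
                                            paste(bad, collapse = ", ")))
    if (!is.finite(gd$shift)) fail(paste0("group_defs$", nm, "$shift"),
                                   "must be finite")
  }
  if (!is.null(config$planted_pqtl)) {
    if (!(config$planted_pqtl$variant %in% ids))
      fail("planted_pqtl$variant", "unknown variant id")
    if (!is.finite(config$planted_pqtl$beta))
      fail("planted_pqtl$beta", "must be finite")
  }
  for (st in c("case", "control")) {
    p <- config$phenotype[[st]]
    if (is.null(p) || length(p) != 2)
      fail(paste0("phenotype$", st), "needs c(log_mean, log_sd)")
    if (p[2] <= 0) fail(paste0("phenotype$", st, "[2]"), "log_sd must be > 0")
  }
  tp <- config$phenotype$total_protein
  if (is.null(tp) || tp[2] <= 0)
    fail("phenotype$total_protein", "needs c(log_mean, log_sd) with log_sd > 0")
  rs <- config$readout_specs
  if (!is.null(rs)) {
    if (any(abs(rs$rho) >= 1)) fail("readout_specs$rho", "|rho| must be < 1")
    if (any(rs$log_sd <= 0)) fail("readout_specs$log_sd", "must be > 0")
  }
  cv <- config$covariates
  if (cv$age_sd <= 0) fail("covariates$age_sd", "must be > 0")
  if (cv$prop_male < 0 || cv$prop_male > 1)
    fail("covariates$prop_male", "must be in [0, 1]")
  if (config$missing_rate < 0 || config$missing_rate >= 1)
    fail("missing_rate", "must be in [0, 1)")
  invisible(config)
}

#' Default simulation configuration
#'
#' The generator's default conditions: 50 cases and 30 controls; a
#' 12-variant gene-region LD block whose pool carries a reference ("none")
#' haplotype, a common core haplotype, a protective haplotype (core +
#' protective variants, higher expression) and a risk haplotype (core + risk
#' variants, expression back near the reference level); a 4-variant upstream
#' regulatory block; a 10-SNP putative-functional panel (MAF 0.15) feeding
#' the genetic risk score; and a 40-SNP trans region containing one planted
#' pQTL of 1.5 case-scale log-SD per allele at MAF 0.2. The normalized
#' phenotype is log-normal with case median 77.8 / control median 113 and
#' case/control log-SD 1.07 / 1.28; functional readout targets follow the
#' observed screen magnitudes (|rho| 0.41-0.66).
#'
#' @param seed master seed.
#' @param n_cases,n_controls cohort sizes.
#' @param planted_beta per-allele planted pQTL effect (log scale).
#' @param missing_rate genotype missingness.
#' @return a \code{sim_config}.
#' @export
default_sim_config <- function(seed = 1L, n_cases = 50L, n_controls = 30L,
                               planted_beta = 1.5 * 1.07,
                               missing_rate = 0) {
  gene_block <- hap_block(
    haplotypes = c("000000000000",        # reference ("none")
                   "111111100000",        # core
                   "111111111000",        # core + protective
                   "111111100011"),       # core + risk
    freqs = c(0.30, 0.45, 0.15, 0.10),
    name = "tnfaip3", chrom = "chr6", start = 138188000L, spacing = 700L,
    gene = "TNFAIP3",
    region_class = c(rep("intronic", 6), "exonic_nonsynonymous",
                     rep("intronic", 3), "intronic", "intergenic"),
    functional = c(rep(FALSE, 6), TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  upstream_block <- hap_block(
    haplotypes = c("0000", "1000", "1100", "1111"),
    freqs = c(0.55, 0.20, 0.15, 0.10),
    name = "upstream", chrom = "chr6", start = 138120000L, spacing = 1500L,
    gene = "TNFAIP3", region_class = "upstream_regulatory",
    functional = TRUE)
  panel <- lapply(seq_len(10), function(i)
    snp_block(0.15, name = paste0("panel", i), chrom = "chr1",
              start = 1000000L + i * 5000L, gene = paste0("GENE", i),
              region_class = if (i %% 2) "upstream_regulatory" else
                "exonic_nonsynonymous",
              functional = TRUE))
  trans_mafs <- rep(c(0.10, 0.20, 0.30, 0.05, 0.15, 0.25, 0.35, 0.40), 5)
  trans <- lapply(seq_len(40), function(i)
    snp_block(trans_mafs[i], name = paste0("ptpn2_", i), chrom = "chr18",
              start = 12810000L + i * 3000L, gene = "PTPN2",
              region_class = "intronic"))
  trans[[20]]$freqs <- c(0.8, 0.2)   # planted pQTL site at MAF 0.2

  core_ids <- paste0("tnfaip3_", 1:7)
  prot_ids <- paste0("tnfaip3_", 8:9)
  risk_ids <- paste0("tnfaip3_", 11:12)

  sim_config(
    n_cases = n_cases, n_controls = n_controls,
    variant_blocks = c(list(gene_block, upstream_block), panel, trans),
    group_defs = list(
      core = list(variants = core_ids, shift = 1.0),
      protective = list(variants = prot_ids, shift = 0.4),
      risk = list(variants = risk_ids, shift = -0.9)),
    planted_pqtl = list(variant = "ptpn2_20_1", beta = planted_beta),
    phenotype = list(
      analyte = "TNFAIP3",
      case = c(log_mean = log(77.8), log_sd = 1.07),
      control = c(log_mean = log(113), log_sd = 1.28),
      total_protein = c(log_mean = log(2), log_sd = 0.15)),
    readout_specs = data.frame(
      stimulus = c("NT", "curdlan", "IL23", "TNFa", "curdlan", "NT",
                   "LPS", "curdlan", "LPS", "curdlan", "LPS", "PGE2",
                   "LPS", "NT", "LPS"),
      analyte = c("pSTAT3", "pSTAT3", "pSTAT3", "pIkBa", "pJNK", "pIkBa",
                  "pIkBa", "pERK", "pERK", "pATF2", "pATF2", "IL-6",
                  "TNF-a", "p65", "p65"),
      rho = c(0.66, 0.66, 0.63, 0.54, 0.52, 0.51,
              0.48, 0.49, 0.43, 0.49, 0.41, 0.44,
              -0.32, 0.30, -0.20),
      log_mean = c(rep(3, 12), 7, 3, 4),
      log_sd = rep(0.8, 15),
      stringsAsFactors = FALSE),
    seed = seed, missing_rate = missing_rate)
}

#' Simulate a cohort dataset
#'
#' Draws two haplotypes per subject per block from each block's pool, codes
#' genotypes additively, builds the latent log phenotype as
#' status-dependent normal noise plus carried group-set shifts plus the
#' planted pQTL effect times allele count, and generates functional readouts
#' whose Spearman correlation with the latent phenotype matches each spec's
#' target through a Gaussian copula on normal scores
#' (\eqn{r_{Pearson} = 2\sin(\pi \rho_S / 6)}).
#'
#' @param config a \code{sim_config}.
#' @return an object of class \code{"cohort"}: list with \code{subjects},
#'   \code{genotypes} (a \code{geno_matrix}), \code{phenotypes},
#'   \code{readouts} and \code{truth} (true haplotypes, latent phenotype and
#'   planted effects; for recovery tests only).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  ids <- sprintf("S%03d", seq_len(n))
  group <- c(rep("case", config$n_cases), rep("control", config$n_controls))

  cv <- config$covariates
  age <- stats::rnorm(n, cv$age_mean, cv$age_sd)
  for (i in which(age < cv$age_min))          # truncated normal, age >= 18
    repeat { age[i] <- stats::rnorm(1, cv$age_mean, cv$age_sd)
             if (age[i] >= cv$age_min) break }
  age <- round(age)
  sex <- ifelse(stats::runif(n) < cv$prop_male, "male", "female")
  on_tnf <- ifelse(group == "case", stats::runif(n) < 0.54, NA)
  onset <- ifelse(group == "case",
                  pmax(18, pmin(age - 1, round(stats::rnorm(n, 27, 9)))), NA)
  duration <- ifelse(group == "case", age - onset, NA)
  subjects <- data.frame(id = ids, group = group, age = age, sex = sex,
                         on_tnf_blocker = on_tnf, age_of_onset = onset,
                         disease_duration = duration, stringsAsFactors = FALSE)

  # genotypes: two haplotypes per subject per block
  h1 <- h2 <- NULL
  variants <- list()
  for (b in config$variant_blocks) {
    i1 <- sample.int(nrow(b$pool), n, replace = TRUE, prob = b$freqs)
    i2 <- sample.int(nrow(b$pool), n, replace = TRUE, prob = b$freqs)
    h1 <- cbind(h1, b$pool[i1, , drop = FALSE])
    h2 <- cbind(h2, b$pool[i2, , drop = FALSE])
    variants[[length(variants) + 1L]] <- data.frame(
      id = paste0(b$name, "_", seq_len(b$n_variants)),
      chrom = b$chrom, pos = b$start + (seq_len(b$n_variants) - 1L) * b$spacing,
      ref = "A", alt = "G", gene = b$gene, region_class = b$region_class,
      functional_flag = b$functional, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, variants)
  codes <- h1 + h2
  rownames(codes) <- rownames(h1) <- rownames(h2) <- ids
  colnames(codes) <- colnames(h1) <- colnames(h2) <- variants$id

  # latent log phenotype with planted effects
  ph <- config$phenotype
  latent <- ifelse(group == "case",
                   stats::rnorm(n, ph$case[1], ph$case[2]),
                   stats::rnorm(n, ph$control[1], ph$control[2]))
  for (gd in config$group_defs) {
    cc <- codes[, gd$variants, drop = FALSE]
    latent <- latent + gd$shift * (rowSums(cc >= 1L) > 0)
  }
  if (!is.null(config$planted_pqtl))
    latent <- latent + config$planted_pqtl$beta *
      codes[, config$planted_pqtl$variant]

  total_protein <- exp(stats::rnorm(n, ph$total_protein[1], ph$total_protein[2]))
  normalized <- exp(latent)
  phenotypes <- data.frame(subject_id = ids, analyte = ph$analyte,
                           raw = normalized * total_protein,
                           total_protein = total_protein,
                           normalized = normalized, stringsAsFactors = FALSE)

  # readouts via Gaussian copula on normal scores of the latent phenotype
  readouts <- NULL
  rs <- config$readout_specs
  if (!is.null(rs) && nrow(rs)) {
    z <- stats::qnorm(rank(latent, ties.method = "first") / (n + 1))
    rows <- lapply(seq_len(nrow(rs)), function(k) {
      r <- 2 * sin(pi * rs$rho[k] / 6)
      w <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
      data.frame(subject_id = ids, stimulus = rs$stimulus[k],
                 analyte = rs$analyte[k],
                 value = exp(rs$log_mean[k] + rs$log_sd[k] * w),
                 stringsAsFactors = FALSE)
    })
    readouts <- do.call(rbind, rows)
  }

  if (config$missing_rate > 0) {
    drop <- stats::runif(length(codes)) < config$missing_rate
    codes[drop] <- NA_integer_
  }

  structure(list(
    subjects = subjects,
    genotypes = genotype_matrix(codes, variants, ids),
    phenotypes = phenotypes,
    readouts = readouts,
    truth = list(hap1 = h1, hap2 = h2, latent = latent,
                 planted_pqtl = config$planted_pqtl,
                 group_defs = config$group_defs, config = config)),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d cases / %d controls, %d variants, %d readout rows\n",
              sum(x$subjects$group == "case"),
              sum(x$subjects$group == "control"),
              ncol(x$genotypes$codes),
              if (is.null(x$readouts)) 0L else nrow(x$readouts)))
  invisible(x)
}
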