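# Shared fixtures and independent oracles used across the test files.

# minimal two-block cohort configuration, fast to simulate
tiny_config <- function(seed = 1L, n_cases = 20L, n_controls = 15L,
                        planted_beta = 0, missing_rate = 0) {
  gene <- hap_block(c("0000", "1111", "1100"), c(0.3, 0.45, 0.25),
                    name = "geneA", gene = "GENEA",
                    region_class = "intronic",
                    functional = c(FALSE, FALSE, TRUE, TRUE))
  snp <- snp_block(0.25, name = "qtl", chrom = "chr2", gene = "GENEB")
  sim_config(
    n_cases = n_cases, n_controls = n_controls,
    variant_blocks = list(gene, snp),
    group_defs = list(core = list(variants = c("geneA_1", "geneA_2"),
                                  shift = 0)),
    planted_pqtl = if (planted_beta != 0)
      list(variant = "qtl_1", beta = planted_beta) else NULL,
    phenotype = list(analyte = "TNFAIP3",
                     case = c(log_mean = 4.3, log_sd = 1.0),
                     control = c(log_mean = 4.7, log_sd = 1.2),
                     total_protein = c(log_mean = log(2), log_sd = 0.15)),
    readout_specs = data.frame(stimulus = c("NT", "LPS"),
                               analyte = c("pSTAT3", "pSTAT3"),
                               rho = c(0.6, -0.4),
                               log_mean = 3, log_sd = 0.8),
    missing_rate = missing_rate, seed = seed)
}

# configuration with no group effects, no planted beta, equal log-means:
# case and control phenotypes are exchangeable
null_config <- function(seed = 1L, n_cases = 20L, n_controls = 20L) {
  cfg <- tiny_config(seed = seed, n_cases = n_cases, n_controls = n_controls)
  cfg$phenotype$case <- c(log_mean = 4.5, log_sd = 1.0)
  cfg$phenotype$control <- c(log_mean = 4.5, log_sd = 1.0)
  cfg
}

# a bare genotype matrix fixture
toy_geno <- function(codes, functional = rep(FALSE, ncol(codes)),
                     region_class = rep("intronic", ncol(codes))) {
  genotype_matrix(
    codes,
    data.frame(id = paste0("v", seq_len(ncol(codes))),
               chrom = "chr1", pos = seq_len(ncol(codes)) * 100L,
               ref = "A", alt = "G", gene = "G1",
               region_class = region_class, functional_flag = functional,
               stringsAsFactors = FALSE),
    subject_ids = paste0("S", seq_len(nrow(codes))))
}

toy_subjects <- function(n, n_cases = ceiling(n / 2), age = NULL, sex = NULL) {
  data.frame(id = paste0("S", seq_len(n)),
             group = rep(c("case", "control"), c(n_cases, n - n_cases)),
             age = if (is.null(age)) seq(30, 70, length.out = n) else age,
             sex = if (is.null(sex)) rep(c("male", "female"), length.out = n)
               else sex,
             stringsAsFactors = FALSE)
}

# --- independent oracles ----------------------------------------------------

# exhaustive permutation p-value via stats::t.test on every label assignment
oracle_perm_p <- function(values, labels) {
  f <- factor(labels)
  n <- length(values)
  n1 <- sum(f == levels(f)[1])
  tt <- function(idx) {
    g1 <- values[idx]; g2 <- values[-idx]
    unname(abs(stats::t.test(g1, g2, var.equal = TRUE)$statistic))
  }
  obs <- tt(which(f == levels(f)[1]))
  combos <- utils::combn(n, n1)
  stats_all <- apply(combos, 2, tt)
  tol <- 1e-8 * (1 + abs(obs))
  sum(stats_all >= obs - tol) / ncol(combos)
}

# HWE conditional distribution by the Wigginton-style recurrence, a route
# independent of the log-factorial evaluation in hwe_exact
oracle_hwe_p <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  rare <- min(nA, na)
  hs <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hs))
  probs[1] <- 1
  if (length(hs) > 1) {
    for (k in seq_len(length(hs) - 1)) {
      h <- hs[k]
      hom_rare <- (rare - h) / 2
      hom_common <- (max(nA, na) - h) / 2
      # P(h+2) / P(h) = 4 * homRare * homCommon / ((h+2)(h+1))
      probs[k + 1] <- probs[k] * 4 * hom_rare * hom_common /
        ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(nAa, hs)]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

# two-site phasing posterior for a single double-heterozygote given the
# unambiguous subjects: Dirichlet-multinomial closed form with +1 prior
oracle_two_site_posterior <- function(count11, count00, count10, count01) {
  a <- c(`11` = count11 + 1, `00` = count00 + 1,
         `10` = count10 + 1, `01` = count01 + 1)
  w_cis <- a[["11"]] * a[["00"]]
  w_trans <- a[["10"]] * a[["01"]]
  w_cis / (w_cis + w_trans)
}
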