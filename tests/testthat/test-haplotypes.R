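# Gibbs phasing, variant-group assignment, group comparisons and the
# Cochran-Armitage trend test.

test_that("unambiguous subjects get posterior 1 and consistent phases", {
  codes <- rbind(S1 = c(0L, 2L, 2L, 0L),   # homozygous everywhere
                 S2 = c(0L, 1L, 0L, 0L),   # single het: orderings equivalent
                 S3 = c(2L, 2L, 2L, 2L))
  phz <- gibbs_phase(codes, n_iter = 200, burn_in = 50, seed = 1)
  expect_equal(phz$phases$posterior, rep(1, 3))
  expect_equal(phz$phases$hap1[1], "0110")
  expect_equal(phz$phases$hap2[1], "0110")
  expect_equal(sort(c(phz$phases$hap1[2], phz$phases$hap2[2])),
               c("0000", "0100"))
  expect_equal(sum(phz$frequencies$freq), 1, tolerance = 1e-9)
})

test_that("two-site double heterozygote matches the closed-form posterior", {
  # 30 subjects homozygous 11/11, 30 homozygous 00/00, one double het:
  # haplotype counts 60/60 for 11 and 00 -> cis phase {11,00} dominates
  codes <- rbind(matrix(2L, 30, 2), matrix(0L, 30, 2), c(1L, 1L))
  rownames(codes) <- paste0("S", 1:61)
  phz <- gibbs_phase(codes, n_iter = 2000, burn_in = 500, seed = 5)
  het <- 61
  expect_equal(sort(c(phz$phases$hap1[het], phz$phases$hap2[het])),
               c("00", "11"))
  oracle <- oracle_two_site_posterior(60, 60, 0, 0)
  expect_lt(abs(phz$phases$posterior[het] - oracle), 0.05)
})

test_that("phases always sum to the genotype and sampler is deterministic", {
  for (seed in 1:3) {
    co <- simulate_cohort(tiny_config(seed = seed, n_cases = 15,
                                      n_controls = 10))
    reg <- subset_variants(co$genotypes, 1:4)
    phz <- gibbs_phase(reg, n_iter = 400, burn_in = 100, seed = seed)
    for (s in seq_len(nrow(phz$phases))) {
      h1 <- as.integer(strsplit(phz$phases$hap1[s], "")[[1]])
      h2 <- as.integer(strsplit(phz$phases$hap2[s], "")[[1]])
      expect_equal(h1 + h2, unname(reg$codes[s, ]))
    }
    expect_equal(sum(phz$frequencies$freq), 1, tolerance = 1e-9)
    phz2 <- gibbs_phase(reg, n_iter = 400, burn_in = 100, seed = seed)
    expect_identical(phz, phz2)
  }
})

test_that("missing sites are imputed for phasing and flagged", {
  codes <- rbind(S1 = c(1L, NA, 0L), S2 = c(0L, 0L, 0L), S3 = c(0L, 0L, 0L),
                 S4 = c(NA, NA, NA))
  expect_message(phz <- gibbs_phase(codes, n_iter = 100, burn_in = 10,
                                    seed = 2), "missing every site")
  expect_equal(phz$phases$n_imputed, c(1L, 0L, 0L, 3L))
  expect_true(is.na(phz$phases$hap1[4]))
  expect_false(anyNA(phz$phases$hap1[1:3]))
})

test_that("switch error is low on two-haplotype LD blocks", {
  # one quick replicate; the 20-seed average runs in the acceptance suite
  cfg <- sim_config(
    n_cases = 40, n_controls = 40,
    variant_blocks = list(hap_block(c("11111", "00000"), c(0.6, 0.4),
                                    name = "blk", gene = "G")),
    phenotype = list(analyte = "X", case = c(1, 0.5), control = c(1, 0.5),
                     total_protein = c(0, 0.1)),
    seed = 7)
  co <- simulate_cohort(cfg)
  phz <- gibbs_phase(co$genotypes, seed = 7)
  expect_lte(switch_error(phz$phases, co$truth$hap1, co$truth$hap2), 0.05)
})

test_that("assign_groups follows the precedence rules and partitions", {
  codes <- rbind(S1 = c(0L, 0L, 0L, 0L),   # none
                 S2 = c(1L, 0L, 0L, 0L),   # core only
                 S3 = c(1L, 2L, 0L, 0L),   # protective + core
                 S4 = c(0L, 1L, 0L, 0L),   # protective only
                 S5 = c(1L, 0L, 1L, 0L),   # risk (beats core)
                 S6 = c(0L, 1L, 1L, 0L))   # protective & risk -> conflict
  g <- toy_geno(codes)
  defs <- list(core = "v1", protective = "v2", risk = "v3")
  lab <- assign_groups(g, defs)
  expect_equal(lab$label, c("none", "core", "protective_plus_core",
                            "protective", "risk", "excluded_conflict"))
  expect_equal(nrow(lab), nrow(codes))   # labels partition the cohort
  expect_error(assign_groups(g, list(core = "nope")), "unknown variant")
})

test_that("group comparison detects a planted deficit and drops conflicts", {
  set.seed(33)
  hits <- vapply(1:30, function(i) {
    lab <- data.frame(subject_id = paste0("S", 1:50),
                      label = rep(c("none", "core"), each = 25),
                      stringsAsFactors = FALSE)
    y <- stats::setNames(c(stats::rnorm(25, 0), stats::rnorm(25, 1)),
                         lab$subject_id)
    cmp <- group_phenotype_comparison(lab, y, n_perm = 400)
    cmp$p_perm <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  lab <- data.frame(subject_id = paste0("S", 1:5),
                    label = c("core", "core", "core", "excluded_conflict",
                              "excluded_conflict"),
                    stringsAsFactors = FALSE)
  y <- stats::setNames(stats::rnorm(5), lab$subject_id)
  expect_equal(nrow(group_phenotype_comparison(lab, y, n_perm = 100)), 0)
})

test_that("cochran_armitage matches the hand formula and prop.trend.test", {
  bal <- cochran_armitage(rbind(c(10, 10, 10), c(10, 10, 10)))
  expect_equal(bal$Z, 0)
  expect_equal(bal$p, 1)
  tbl <- rbind(cases = c(10, 20, 20), controls = c(30, 15, 5))
  got <- cochran_armitage(tbl)
  ref <- stats::prop.trend.test(tbl[1, ], colSums(tbl), score = 0:2)
  expect_equal(got$Z^2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  # 2x2 collapse equals 2x3 with an empty middle column (same scores)
  t22 <- rbind(c(12, 8), c(5, 15))
  t23 <- cbind(t22[, 1], c(0, 0), t22[, 2])
  expect_equal(cochran_armitage(t22, scores = c(0, 2))$Z,
               cochran_armitage(t23)$Z, tolerance = 1e-12)
  expect_equal(cochran_armitage(rbind(c(5, 0, 0), c(3, 0, 0)))$p, 1)
})
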