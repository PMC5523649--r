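# Exact HWE test and filter, burdens, risk score, KS comparison.

test_that("hwe_exact handles closed-form and extreme configurations", {
  expect_equal(as.numeric(hwe_exact(50, 0, 0)), 1)   # monomorphic
  # 2 A and 2 a alleles: heterozygote counts {0, 2} with probabilities
  # {1/3, 2/3}; observing h = 0 gives p = 1/3
  d <- attr(hwe_exact(1, 0, 1), "distribution")
  expect_equal(d$prob, c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(as.numeric(hwe_exact(1, 0, 1)), 1 / 3)
  expect_lt(as.numeric(hwe_exact(0, 100, 0)), 1e-6)  # extreme het excess
  expect_error(hwe_exact(-1, 0, 1), "non-negative")
})

test_that("hwe_exact equals the recurrence oracle on a broad sweep", {
  # exhaustive over all tables with n <= 25 here; the n <= 60 sweep runs in
  # the acceptance suite
  for (n in 1:25) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(as.numeric(hwe_exact(nAA, nAa, naa)),
                   oracle_hwe_p(nAA, nAa, naa), tolerance = 1e-10)
    }
  }
})

test_that("hwe conditional probabilities sum to one", {
  set.seed(6)
  for (i in 1:50) {
    counts <- as.vector(stats::rmultinom(1, sample(10:500, 1), c(.3, .4, .3)))
    d <- attr(hwe_exact(counts[1], counts[2], counts[3]), "distribution")
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  }
})

test_that("exact test is conservative under HWE sampling", {
  set.seed(41)
  p_vals <- vapply(1:500, function(i) {
    haps <- stats::rbinom(160, 1, 0.2)
    g <- haps[1:80] + haps[81:160]
    as.numeric(hwe_exact(sum(g == 0), sum(g == 1), sum(g == 2)))
  }, numeric(1))
  se3 <- 3 * sqrt(0.05 * 0.95 / 500)
  expect_lte(mean(p_vals < 0.05), 0.05 + se3)
})

test_that("hwe_filter excludes on either stratum and reports all strata", {
  set.seed(2)
  # variant 1 in HWE everywhere; variant 2 all-het within cases
  n <- 60
  codes <- cbind(v_ok <- stats::rbinom(n, 1, 0.3) + stats::rbinom(n, 1, 0.3),
                 c(rep(1L, 30), stats::rbinom(30, 1, 0.3) +
                     stats::rbinom(30, 1, 0.3)))
  g <- toy_geno(codes)
  subj <- toy_subjects(n, n_cases = 30)
  hw <- hwe_filter(g, subj, threshold = 1e-5)
  expect_equal(as.numeric(hwe_exact(0, 30, 0)) < 1e-5, TRUE)
  expect_equal(hw$kept$variants$id, "v1")
  expect_equal(nrow(hw$results), 2 * 3)   # both variants, three strata
  expect_true(all(hw$results$excluded[hw$results$variant_id == "v2"]))
})

test_that("raising the threshold never un-excludes variants", {
  set.seed(9)
  codes <- matrix(stats::rbinom(40 * 30, 2, 0.3), nrow = 40)
  codes[, 1] <- 1L   # pathological all-het column
  g <- toy_geno(codes)
  subj <- toy_subjects(40)
  excl <- vapply(c(1e-8, 1e-5, 1e-3, 0.05, 0.5),
                 function(th) hwe_filter(g, subj, th)$n_excluded, numeric(1))
  expect_true(all(diff(excl) >= 0))
})

test_that("burden counts loci (not alleles) and conserves totals", {
  codes <- rbind(S1 = c(0L, 0L, 0L, 0L),
                 S2 = c(1L, 1L, 1L, 2L),
                 S3 = c(2L, NA, 0L, 1L))
  g <- toy_geno(codes)
  b <- burden_by_region(g)
  expect_equal(unname(b), c(0L, 4L, 2L))          # locus count, hom = 1 locus
  bd <- burden_by_region(g, mode = "dosage")
  expect_equal(unname(bd), c(0L, 5L, 3L))
  # conservation: per-subject burdens sum to matrix-wide nonzero codes
  expect_equal(sum(b), sum(g$codes >= 1, na.rm = TRUE))
  # histogram sums to cohort size per group
  subj <- toy_subjects(3, n_cases = 2)
  h <- attr(burden_by_region(g, subjects = subj), "histogram")
  expect_equal(sum(h$case), 2)
  expect_equal(sum(h$control), 1)
})

test_that("genetic_risk_score restricts to flagged variants", {
  codes <- rbind(S1 = c(0L, 2L, 1L), S2 = c(1L, 0L, 0L), S3 = c(0L, 0L, 0L))
  g <- toy_geno(codes, functional = c(FALSE, TRUE, TRUE))
  expect_equal(unname(genetic_risk_score(g)), c(2L, 0L, 0L))
  g0 <- toy_geno(codes)
  expect_error(genetic_risk_score(g0), "functional_flag")
})

test_that("risk-score permutation p is well calibrated under the null", {
  set.seed(13)
  p_vals <- vapply(1:100, function(i) {
    codes <- matrix(stats::rbinom(40 * 8, 2, 0.2), nrow = 40)
    g <- toy_geno(codes, functional = rep(TRUE, 8))
    grs <- genetic_risk_score(g)
    permuted_mean_test(grs, toy_subjects(40)$group, n_perm = 200)$p_perm
  }, numeric(1))
  # roughly uniform: mean near 0.5, no mass collapse at 0
  expect_gt(mean(p_vals), 0.35)
  expect_lt(mean(p_vals), 0.65)
  expect_lt(mean(p_vals <= 0.05), 0.15)
})

test_that("ks_two_sample matches the ECDF supremum", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 11, 12))$D, 1)
  a <- c(0.1, 0.5, 0.9, 1.4)
  b <- c(0.3, 0.7, 1.1)
  grid <- sort(c(a, b))
  d_hand <- max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
  expect_equal(ks_two_sample(a, b)$D, d_hand)
  expect_error(ks_two_sample(numeric(0), 1:3), "nonempty")
})
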