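# Logistic and linear association scans against direct matrix oracles,
# null calibration and permutation verification.

# design matrix matching the scans' internal coding (standardized age,
# 0/1 sex)
scan_design <- function(gt, subjects) {
  age <- (subjects$age - mean(subjects$age)) / stats::sd(subjects$age)
  cbind(1, gt, age, as.integer(subjects$sex == "male"))
}

test_that("pqtl_scan equals the normal-equations OLS oracle", {
  set.seed(14)
  n <- 10
  subj <- toy_subjects(n)
  gt <- c(0L, 1L, 2L, 0L, 1L, 0L, 2L, 1L, 0L, 1L)
  y <- stats::rnorm(n, mean = gt)
  g <- toy_geno(matrix(gt, ncol = 1))
  res <- pqtl_scan(g, stats::setNames(y, subj$id), subj, stratum = "all")
  X <- scan_design(gt, subj)
  beta_hat <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% beta_hat
  sigma2 <- sum(resid^2) / (n - 4)
  se_hat <- sqrt(sigma2 * solve(crossprod(X))[2, 2])
  expect_equal(res$beta, beta_hat[2], tolerance = 1e-8)
  expect_equal(res$se, se_hat, tolerance = 1e-8)
  expect_equal(res$p_asymptotic,
               2 * stats::pt(-abs(beta_hat[2] / se_hat), df = n - 4),
               tolerance = 1e-8)
})

test_that("logistic_scan equals a Newton-iteration IRLS oracle", {
  set.seed(15)
  n <- 10
  subj <- toy_subjects(n, n_cases = 5,
                       age = c(45, 62, 38, 55, 50, 41, 60, 47, 58, 52))
  gt <- c(2L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L)
  g <- toy_geno(matrix(gt, ncol = 1))
  res <- logistic_scan(g, subj)
  X <- scan_design(gt, subj)
  y <- as.integer(subj$group == "case")
  b <- rep(0, 4)
  for (i in 1:60) {             # Newton-Raphson to machine precision
    eta <- as.vector(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    step <- solve(crossprod(X, X * W), crossprod(X, y - mu))
    b <- b + step
    if (max(abs(step)) < 1e-14) break
  }
  mu <- as.vector(1 / (1 + exp(-X %*% b)))
  se <- sqrt(diag(solve(crossprod(X, X * (mu * (1 - mu))))))
  expect_true(res$estimable)
  expect_equal(res$beta, unname(b[2]), tolerance = 1e-8)
  expect_equal(res$se, unname(se[2]), tolerance = 1e-6)
})

test_that("degenerate variants are flagged unestimable, never a crash", {
  n <- 30
  subj <- toy_subjects(n)
  codes <- cbind(rep(0L, n),                         # monomorphic
                 stats::rbinom(n, 2, 0.4))
  g <- toy_geno(codes)
  y <- stats::setNames(stats::rnorm(n), subj$id)
  lin <- pqtl_scan(g, y, subj)
  expect_false(lin$estimable[1])
  expect_true(is.na(lin$beta[1]))
  expect_true(lin$estimable[2])
  log_res <- logistic_scan(g, subj)
  expect_false(log_res$estimable[1])
  # complete separation
  sep <- toy_geno(matrix(as.integer(subj$group == "case"), ncol = 1))
  expect_false(logistic_scan(sep, subj)$estimable[1])
})

test_that("strata partition n_used for fully observed variants", {
  set.seed(16)
  co <- simulate_cohort(tiny_config(seed = 16))
  y <- stats::setNames(log(co$phenotypes$normalized), co$phenotypes$subject_id)
  res_all <- pqtl_scan(co$genotypes, y, co$subjects, "all")
  res_ca <- pqtl_scan(co$genotypes, y, co$subjects, "case")
  res_co <- pqtl_scan(co$genotypes, y, co$subjects, "control")
  expect_equal(res_all$n_used, res_ca$n_used + res_co$n_used)
})

test_that("scans are invariant to subject row order", {
  set.seed(18)
  co <- simulate_cohort(tiny_config(seed = 18))
  y <- stats::setNames(log(co$phenotypes$normalized), co$phenotypes$subject_id)
  res1 <- pqtl_scan(co$genotypes, y, co$subjects)
  perm <- sample(nrow(co$genotypes$codes))
  g2 <- genotype_matrix(co$genotypes$codes[perm, ], co$genotypes$variants,
                        co$genotypes$subject_ids[perm])
  res2 <- pqtl_scan(g2, y, co$subjects)
  expect_equal(res1$beta, res2$beta, tolerance = 1e-12)
  expect_equal(res1$p_asymptotic, res2$p_asymptotic, tolerance = 1e-12)
  l1 <- logistic_scan(co$genotypes, co$subjects)
  l2 <- logistic_scan(g2, co$subjects)
  expect_equal(l1$beta, l2$beta, tolerance = 1e-10)
})

test_that("null logistic scan p-values are approximately uniform", {
  set.seed(19)
  n <- 400
  subj <- toy_subjects(n, n_cases = 200,
                       age = round(stats::rnorm(n, 50, 10)),
                       sex = sample(c("male", "female"), n, TRUE))
  codes <- matrix(stats::rbinom(n * 120, 2, 0.3), nrow = n)
  g <- toy_geno(codes)
  res <- logistic_scan(g, subj)
  ks <- stats::ks.test(res$p_asymptotic, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("planted log-odds ratio is recovered on average", {
  set.seed(23)
  betas <- vapply(1:25, function(i) {
    n <- 400
    gt <- stats::rbinom(n, 2, 0.3)
    age <- round(stats::rnorm(n, 50, 10))
    sex <- sample(c("male", "female"), n, TRUE)
    eta <- -0.6 + 1.0 * gt
    y <- stats::rbinom(n, 1, 1 / (1 + exp(-eta)))
    subj <- data.frame(id = paste0("S", 1:n),
                       group = ifelse(y == 1, "case", "control"),
                       age = age, sex = sex, stringsAsFactors = FALSE)
    g <- toy_geno(matrix(as.integer(gt), ncol = 1))
    logistic_scan(g, subj)$beta
  }, numeric(1))
  expect_lt(abs(mean(betas) - 1.0), 0.3)
})

test_that("permuted top-hit p agrees with the asymptotic p for null variants", {
  set.seed(26)
  n <- 60
  subj <- toy_subjects(n, n_cases = 30,
                       age = round(stats::rnorm(n, 50, 10)),
                       sex = sample(c("male", "female"), n, TRUE))
  codes <- matrix(stats::rbinom(n * 12, 2, 0.3), nrow = n)
  g <- toy_geno(codes)
  y <- stats::setNames(stats::rnorm(n), subj$id)
  res <- pqtl_scan(g, y, subj)
  ver <- permute_top_hits(res, g, y, subj, top_k = 12, n_perm = 4000,
                          seed = 27)
  mid <- which(ver$p_asymptotic > 0.05 & ver$p_asymptotic < 0.5)
  expect_gt(length(mid), 0)
  expect_true(all(abs(ver$p_permuted[mid] - ver$p_asymptotic[mid]) < 0.05))
})

test_that("a strong planted effect hits the permutation resolution floor", {
  set.seed(28)
  n <- 80
  subj <- toy_subjects(n, n_cases = 40)
  gt <- stats::rbinom(n, 2, 0.3)
  y <- stats::setNames(2 * gt + stats::rnorm(n), subj$id)
  g <- toy_geno(matrix(as.integer(gt), ncol = 1))
  res <- pqtl_scan(g, y, subj)
  ver <- permute_top_hits(res, g, y, subj, top_k = 1, n_perm = 1000, seed = 2)
  expect_equal(ver$p_permuted[1], 0)
  expect_lte(ver$p_permuted_add1[1], 1 / 1000 + 1e-9)
  # Freedman-Lane mode agrees at this effect size
  fl <- permute_top_hits(res, g, y, subj, top_k = 1, n_perm = 500, seed = 3,
                         scheme = "freedman_lane")
  expect_equal(fl$p_permuted[1], 0)
})
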