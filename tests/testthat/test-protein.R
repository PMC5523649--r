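# Phenotype normalization, Box-Cox, Spearman screening, clustering and
# low-expresser flags.

test_that("normalize_phenotype is the guarded ratio", {
  expect_equal(normalize_phenotype(500, 2), 250)
  expect_equal(normalize_phenotype(0, 2), 0)
  expect_error(normalize_phenotype(500, 0, subject_id = "S1"), "S1")
})

test_that("shapiro_wilk distinguishes Gaussian from log-normal data", {
  set.seed(4)
  x <- stats::rnorm(500)
  expect_gt(shapiro_wilk(x)$p, 0.05)
  expect_lt(shapiro_wilk(exp(x))$p, 0.01)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "between 3 and 5000")
})

test_that("boxcox_fit recovers the generating exponent", {
  set.seed(21)
  lognorm <- exp(stats::rnorm(500))
  expect_lt(abs(boxcox_fit(lognorm)$lambda - 0), 0.15)
  gauss <- stats::rnorm(500, mean = 10, sd = 1)
  expect_lt(abs(boxcox_fit(gauss)$lambda - 1), 0.5)
  expect_error(boxcox_fit(c(-1, 2, 3)), "positive")
  expect_error(boxcox_fit(1:10, lambda_grid = seq(0, 1, 0.1)), "span")
})

test_that("boxcox_fit agrees with the MASS profile-likelihood maximizer", {
  skip_if_not_installed("MASS")
  set.seed(8)
  y <- exp(stats::rnorm(300, sd = 0.7)) + 2
  grid <- seq(-2, 2, by = 0.01)
  ours <- boxcox_fit(y, grid)$lambda
  bc <- MASS::boxcox(y ~ 1, lambda = grid, plotit = FALSE)
  expect_equal(ours, bc$x[which.max(bc$y)], tolerance = 1e-8)
})

test_that("boxcox_transform closed forms hold", {
  y <- c(1, 2, 5)
  expect_equal(boxcox_transform(y, 1), y - 1)
  expect_equal(boxcox_transform(y, 0), log(y))
  expect_equal(boxcox_transform(y, 2), (y^2 - 1) / 2)
})

test_that("offset_for_boxcox is half the smallest positive value", {
  expect_equal(offset_for_boxcox(c(0, 4, 10)), 2)
  expect_equal(offset_for_boxcox(c(1, 2)), 0)
})

test_that("spearman matches the rank formula and is monotone-invariant", {
  got <- spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(got$rho, 0.8)       # 1 - 6*2 / (4*15)
  expect_equal(spearman(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman(1:6, rev(1:6))$rho, -1)
  set.seed(3)
  x <- stats::rnorm(25); y <- stats::rnorm(25)
  base <- spearman(x, y)
  warped <- spearman(x, exp(3 * y))   # strictly increasing transform
  expect_equal(base$rho, warped$rho)
  expect_equal(base$p, warped$p)
  expect_error(spearman(1:5, rep(2, 5)), "constant")
})

test_that("spearman p agrees with cor.test's t approximation", {
  set.seed(12)
  x <- stats::rnorm(40); y <- x + stats::rnorm(40)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  got <- spearman(x, y)
  expect_equal(got$rho, unname(ref$estimate))
  expect_equal(got$p, ref$p.value, tolerance = 1e-6)
})

test_that("fold_induction is the guarded stimulated/NT ratio", {
  expect_equal(fold_induction(10, 10), 1)
  expect_equal(fold_induction(30, 10), 3)
  expect_warning(out <- fold_induction(5, 0), "dropped")
  expect_true(is.na(out))
})

test_that("correlation_screen applies Bonferroni over performed tests", {
  set.seed(17)
  co <- simulate_cohort(tiny_config(seed = 17, n_cases = 40, n_controls = 40))
  ph <- data.frame(subject_id = co$phenotypes$subject_id,
                   value = co$phenotypes$normalized)
  scr <- correlation_screen(ph, co$readouts)
  m <- attr(scr, "n_tests")
  expect_equal(nrow(scr), m)
  expect_equal(scr$significant_experimentwise, scr$p <= 0.05 / m)
  # Bonferroni count never exceeds the uncorrected count
  expect_lte(sum(scr$significant_experimentwise), sum(scr$p <= 0.05))
  expect_false(is.unsorted(scr$p))
  # the targeted NT/pSTAT3 cell is recovered with the right sign
  expect_gt(scr$rho[scr$stimulus == "NT" & scr$output == "pSTAT3"], 0.3)
  # independent noise readout is not experiment-wise significant
  noise <- data.frame(subject_id = ph$subject_id, stimulus = "NT",
                      analyte = "noise",
                      value = stats::rnorm(nrow(ph), 10))
  scr2 <- correlation_screen(ph, rbind(co$readouts, noise))
  expect_false(scr2$significant_experimentwise[
    scr2$output == "noise" & scr2$stimulus == "NT"])
})

test_that("single-test screen reduces the threshold to alpha", {
  ph <- data.frame(subject_id = paste0("S", 1:10), value = 1:10)
  rd <- data.frame(subject_id = paste0("S", 1:10), stimulus = "NT",
                   analyte = "pSTAT3", value = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  scr <- correlation_screen(ph, rd, alpha = 0.05)
  expect_equal(attr(scr, "n_tests"), 1L)
  expect_equal(scr$significant_experimentwise, scr$p <= 0.05)
})

test_that("cluster_phenotype separates point masses and accounts all SS", {
  x <- c(rep(50, 10), rep(400, 12))
  for (m in c("kmeans", "upgma")) {
    cl <- cluster_phenotype(x, m, k_range = 1:2, seed = 1)
    lab <- cl$labels[["2"]]
    expect_equal(length(unique(lab[1:10])), 1)
    expect_equal(length(unique(lab[11:22])), 1)
    expect_false(lab[1] == lab[11])
    expect_equal(cl$wss[["1"]], sum((x - mean(x))^2))
  }
  expect_error(cluster_phenotype(1:3, "kmeans", k_range = 1:5), "k exceeds")
})

test_that("1-D Gaussian mixture is recovered at k = 2", {
  set.seed(31)
  agree <- vapply(1:25, function(i) {
    truth <- rep(1:2, each = 40)
    x <- stats::rnorm(80, mean = c(100, 300)[truth], sd = 30)
    lab <- cluster_phenotype(x, "kmeans", k_range = 2, seed = i)$labels[["2"]]
    max(mean(lab == truth), mean(lab == 3 - truth))
  }, numeric(1))
  expect_gte(mean(agree >= 0.9), 0.9)
})

test_that("low_expresser_flags uses the interpolated control quartile", {
  flags <- low_expresser_flags(c(100, 200, 300, 400), c(150, 175, 176, 500))
  expect_equal(attr(flags, "threshold"), 175)
  expect_equal(as.logical(flags), c(TRUE, TRUE, FALSE, FALSE))
  # all cases above the control maximum
  expect_false(any(low_expresser_flags(c(1, 2, 3, 4), c(5, 6))))
  expect_error(low_expresser_flags(c(1, 2), c(3)), "4 control")
})
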