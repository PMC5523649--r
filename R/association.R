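# Per-variant association scans: additive logistic regression for
# case/control status, linear regression for protein-QTL effects, both
# adjusted for age and sex, with a permutation routine verifying top hits.

# shared covariate builder: sex coded 0/1 (male = 1), age standardized for
# conditioning; the genotype coefficient is unaffected by covariate scaling
.scan_covariates <- function(subjects, ids) {
  idx <- match(ids, subjects$id)
  if (anyNA(idx)) stop("subjects table does not cover all genotyped subjects")
  age <- subjects$age[idx]
  sex <- as.integer(subjects$sex[idx] == "male")
  age_std <- if (stats::sd(age) > 0) (age - mean(age)) / stats::sd(age) else age * 0
  data.frame(age = age_std, sex = sex)
}

.unestimable <- function(id, model, stratum, n_used) {
  data.frame(variant_id = id, model = model, stratum = stratum,
             beta = NA_real_, se = NA_real_, stat = NA_real_,
             p_asymptotic = NA_real_, n_used = n_used,
             estimable = FALSE, stringsAsFactors = FALSE)
}

#' Case/control logistic association scan
#'
#' Per variant, fits \code{status ~ genotype + age + sex} by IRLS
#' ([stats::glm()], binomial) under the additive genetic model (genotype =
#' alternate-allele count) and reports the Wald z and asymptotic p for the
#' genotype coefficient. Subjects missing a variant's genotype are dropped
#' for that variant (complete-case; \code{n_used} records the count).
#' Monomorphic variants, non-converged fits and (quasi-)separated fits are
#' flagged unestimable rather than crashing.
#'
#' @param g a \code{geno_matrix} (HWE-filtered upstream).
#' @param subjects data.frame with \code{id}, \code{group}
#'   (\code{"case"}/\code{"control"}), \code{age}, \code{sex}
#'   (\code{"male"}/\code{"female"}).
#' @return data.frame, one row per variant: \code{variant_id}, \code{model},
#'   \code{stratum}, \code{beta} (per alt allele, log-odds), \code{se},
#'   \code{stat} (Wald z), \code{p_asymptotic}, \code{n_used},
#'   \code{estimable}.
#' @export
logistic_scan <- function(g, subjects) {
  stopifnot(inherits(g, "geno_matrix"))
  cov <- .scan_covariates(subjects, g$subject_ids)
  y <- as.integer(subjects$group[match(g$subject_ids, subjects$id)] == "case")
  if (length(unique(y)) < 2) stop("both cases and controls required")
  out <- lapply(seq_len(ncol(g$codes)), function(j) {
    gt <- g$codes[, j]
    keep <- !is.na(gt)
    n_used <- sum(keep)
    id <- g$variants$id[j]
    if (n_used < 5 || stats::sd(gt[keep]) == 0 ||
        length(unique(y[keep])) < 2)
      return(.unestimable(id, "logistic", "all", n_used))
    dat <- data.frame(y = y[keep], gt = gt[keep],
                      age = cov$age[keep], sex = cov$sex[keep])
    fit <- tryCatch(
      withCallingHandlers(
        stats::glm(y ~ gt + age + sex, family = stats::binomial(), data = dat,
                   control = stats::glm.control(epsilon = 1e-12, maxit = 50)),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      return(.unestimable(id, "logistic", "all", n_used))
    sm <- summary(fit)$coefficients
    if (!("gt" %in% rownames(sm)))
      return(.unestimable(id, "logistic", "all", n_used))
    beta <- sm["gt", "Estimate"]; se <- sm["gt", "Std. Error"]
    # separation heuristic: runaway coefficient or absurd standard error
    if (!is.finite(se) || se > 1e3 || abs(beta) > 15)
      return(.unestimable(id, "logistic", "all", n_used))
    data.frame(variant_id = id, model = "logistic", stratum = "all",
               beta = beta, se = se, stat = beta / se,
               p_asymptotic = 2 * stats::pnorm(-abs(beta / se)),
               n_used = n_used, estimable = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Protein-QTL linear association scan
#'
#' Per variant, ordinary least squares \code{phenotype ~ genotype + age +
#' sex} on the chosen stratum (cases, controls or the combined group), with
#' the t statistic and asymptotic p for the genotype coefficient. The
#' phenotype is expected to be normalized and Box-Cox transformed already.
#' Variants with a constant genotype in the stratum, or with fewer than 5
#' residual degrees of freedom, are flagged unestimable.
#'
#' @param g a \code{geno_matrix}.
#' @param phenotype named numeric vector of transformed phenotype values,
#'   names = subject ids (or a data.frame with \code{subject_id},
#'   \code{value}).
#' @param subjects subjects data.frame (see [logistic_scan()]).
#' @param stratum \code{"all"}, \code{"case"} or \code{"control"}.
#' @return data.frame as in [logistic_scan()] with \code{model = "linear"};
#'   rows are in variant order, sortable by \code{p_asymptotic}.
#' @export
pqtl_scan <- function(g, phenotype, subjects, stratum = c("all", "case", "control")) {
  stopifnot(inherits(g, "geno_matrix"))
  stratum <- match.arg(stratum)
  if (is.data.frame(phenotype))
    phenotype <- stats::setNames(phenotype$value, phenotype$subject_id)
  grp <- subjects$group[match(g$subject_ids, subjects$id)]
  in_stratum <- if (stratum == "all") rep(TRUE, length(grp)) else grp == stratum
  if (!any(in_stratum)) stop("stratum '", stratum, "' is empty")
  cov <- .scan_covariates(subjects, g$subject_ids)
  y <- unname(phenotype[g$subject_ids])

  out <- lapply(seq_len(ncol(g$codes)), function(j) {
    gt <- g$codes[, j]
    keep <- in_stratum & !is.na(gt) & is.finite(y)
    n_used <- sum(keep)
    id <- g$variants$id[j]
    if (n_used == 0 || stats::sd(gt[keep]) == 0)
      return(.unestimable(id, "linear", stratum, n_used))
    X <- cbind(1, gt[keep], cov$age[keep], cov$sex[keep])
    df_resid <- n_used - qr(X)$rank
    if (df_resid < 5)
      return(.unestimable(id, "linear", stratum, n_used))
    fit <- stats::lm.fit(X, y[keep])
    sigma2 <- sum(fit$residuals^2) / df_resid
    XtXinv <- chol2inv(chol(crossprod(X[, seq_len(fit$rank), drop = FALSE])))
    se <- sqrt(sigma2 * XtXinv[2, 2])
    beta <- fit$coefficients[2]
    tt <- beta / se
    data.frame(variant_id = id, model = "linear", stratum = stratum,
               beta = beta, se = se, stat = tt,
               p_asymptotic = 2 * stats::pt(-abs(tt), df = df_resid),
               n_used = n_used, estimable = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Permutation verification of the top pQTL hits
#'
#' For each of the \code{top_k} variants ranked by asymptotic p, the
#' phenotype vector is permuted across subjects (genotypes and covariates
#' stay attached to their subjects), the same age/sex-adjusted regression is
#' refit for every permutation, and the permuted p is the fraction of
#' permuted \eqn{|t|} at or above the observed \eqn{|t|}. A Freedman-Lane
#' mode (permuting covariate-model residuals and adding back the covariate
#' fit) is available for covariate-respecting inference; the default is the
#' simple phenotype shuffle.
#'
#' @param results data.frame from [pqtl_scan()].
#' @param g,phenotype,subjects,stratum as in [pqtl_scan()].
#' @param top_k number of top hits to verify (default 30).
#' @param n_perm permutations per variant (default 10000).
#' @param seed integer seed.
#' @param scheme \code{"simple"} or \code{"freedman_lane"}.
#' @return \code{results} with columns \code{p_permuted} and
#'   \code{p_permuted_add1} filled for the verified variants (zero exceedance
#'   is reported as 0; the \eqn{(b+1)/(B+1)} column never is).
#' @export
permute_top_hits <- function(results, g, phenotype, subjects,
                             stratum = "all", top_k = 30L, n_perm = 10000L,
                             seed = NULL, scheme = c("simple", "freedman_lane")) {
  scheme <- match.arg(scheme)
  stopifnot(top_k >= 1)
  if (is.data.frame(phenotype))
    phenotype <- stats::setNames(phenotype$value, phenotype$subject_id)
  if (!is.null(seed)) set.seed(seed)
  est <- which(results$estimable)
  top <- est[order(results$p_asymptotic[est])][seq_len(min(top_k, length(est)))]
  results$p_permuted <- NA_real_
  results$p_permuted_add1 <- NA_real_

  grp <- subjects$group[match(g$subject_ids, subjects$id)]
  in_stratum <- if (stratum == "all") rep(TRUE, length(grp)) else grp == stratum
  cov <- .scan_covariates(subjects, g$subject_ids)
  y_all <- unname(phenotype[g$subject_ids])

  for (r in top) {
    j <- match(results$variant_id[r], g$variants$id)
    gt <- g$codes[, j]
    keep <- in_stratum & !is.na(gt) & is.finite(y_all)
    X <- cbind(1, gt[keep], cov$age[keep], cov$sex[keep])
    y <- y_all[keep]
    n <- length(y)
    qrX <- qr(X)
    df_resid <- n - qrX$rank
    XtXinv22 <- chol2inv(chol(crossprod(X)))[2, 2]

    t_of <- function(Y) {
      # Y: n x B matrix of (permuted) responses; vectorized OLS t for column 2
      coefs <- qr.coef(qrX, Y)
      res <- Y - X %*% coefs
      sig2 <- colSums(res^2) / df_resid
      coefs[2, ] / sqrt(sig2 * XtXinv22)
    }
    t_obs <- t_of(matrix(y, ncol = 1))[1]

    if (scheme == "freedman_lane") {
      Z <- X[, -2, drop = FALSE]
      fitted_z <- qr.fitted(qr(Z), y)
      res_z <- y - fitted_z
    }
    tol <- 1e-8 * (1 + abs(t_obs))
    b <- 0L
    remaining <- as.integer(n_perm)
    while (remaining > 0L) {     # chunked so n_perm = 1e6 stays in memory
      nb <- min(remaining, 50000L)
      perm_idx <- replicate(nb, sample.int(n))
      Y <- if (scheme == "simple") matrix(y[perm_idx], nrow = n) else
        fitted_z + matrix(res_z[perm_idx], nrow = n)
      b <- b + sum(abs(t_of(Y)) >= abs(t_obs) - tol)
      remaining <- remaining - nb
    }
    results$p_permuted[r] <- b / n_perm
    results$p_permuted_add1[r] <- (b + 1) / (n_perm + 1)
  }
  results
}
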