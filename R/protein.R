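# Protein phenotype handling: lysate normalization, normality checking,
# Box-Cox transformation, correlation screening and exploratory clustering.

#' Normalize an analyte level to total lysate protein
#'
#' @param raw analyte concentration (assay units).
#' @param total_protein total lysate protein concentration; must be positive.
#' @param subject_id optional identifier used in error messages.
#' @return the ratio \code{raw / total_protein}.
#' @export
normalize_phenotype <- function(raw, total_protein, subject_id = NULL) {
  if (any(!is.finite(total_protein)) || any(total_protein <= 0)) {
    who <- if (is.null(subject_id)) "" else
      paste0(" for subject ",
             paste(subject_id[which(total_protein <= 0)], collapse = ", "))
    stop("total_protein must be positive", who)
  }
  raw / total_protein
}

#' Shapiro-Wilk normality test
#'
#' Thin guard around [stats::shapiro.test()] used to decide whether a
#' phenotype needs a Box-Cox transformation before linear modelling.
#'
#' @param values numeric vector, 3 to 5000 non-constant observations.
#' @return list with \code{W} and \code{p}.
#' @export
shapiro_wilk <- function(values) {
  x <- as.numeric(values[is.finite(values)])
  if (length(x) < 3 || length(x) > 5000)
    stop("shapiro_wilk requires between 3 and 5000 finite observations")
  if (stats::sd(x) == 0) stop("shapiro_wilk: input is constant")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Fit a Box-Cox exponent by profile likelihood
#'
#' Chooses the power-transform exponent \eqn{\lambda} maximizing the Gaussian
#' profile log-likelihood
#' \deqn{\ell(\lambda) = -\tfrac{n}{2}\log\hat\sigma^2_\lambda +
#'   (\lambda - 1)\sum_i \log y_i}
#' over a grid, where \eqn{\hat\sigma^2_\lambda} is the ML variance of the
#' transformed values. Values must be strictly positive; callers with zero or
#' negative values should add an offset first (see \code{offset_for_boxcox}).
#'
#' @param values positive numeric vector.
#' @param lambda_grid candidate exponents; must span at least \eqn{[-2, 2]}.
#' @return list with \code{lambda} (the maximizing grid point),
#'   \code{loglik} (profile log-likelihood at each grid point) and
#'   \code{grid}.
#' @export
boxcox_fit <- function(values, lambda_grid = seq(-2, 2, by = 0.01)) {
  y <- as.numeric(values)
  if (any(!is.finite(y)) || any(y <= 0))
    stop("boxcox_fit requires strictly positive finite values; ",
         "offset the data first")
  if (min(lambda_grid) > -2 || max(lambda_grid) < 2)
    stop("lambda_grid must span at least [-2, 2]")
  n <- length(y)
  slog <- sum(log(y))
  ll <- vapply(lambda_grid, function(lam) {
    z <- boxcox_transform(y, lam)
    s2 <- sum((z - mean(z))^2) / n
    -n / 2 * log(s2) + (lam - 1) * slog
  }, numeric(1))
  list(lambda = lambda_grid[which.max(ll)], loglik = ll, grid = lambda_grid)
}

#' Apply a Box-Cox power transform
#'
#' \eqn{(y^\lambda - 1)/\lambda} for \eqn{\lambda \ne 0}, \eqn{\log y} for
#' \eqn{\lambda = 0}.
#'
#' @param values positive numeric vector.
#' @param lambda exponent.
#' @return transformed vector.
#' @export
boxcox_transform <- function(values, lambda) {
  if (any(values <= 0, na.rm = TRUE))
    stop("boxcox_transform requires strictly positive values")
  if (abs(lambda) < 1e-12) log(values) else (values^lambda - 1) / lambda
}

#' Offset recommended before Box-Cox when non-positive values are present
#'
#' Half the smallest positive value; returns 0 when all values are already
#' positive. The offset used is part of the transform's provenance and should
#' be recorded alongside lambda.
#'
#' @param values numeric vector.
#' @return scalar offset.
#' @export
offset_for_boxcox <- function(values) {
  v <- values[is.finite(values)]
  if (all(v > 0)) return(0)
  pos <- v[v > 0]
  if (!length(pos)) stop("no positive values; cannot choose an offset")
  min(pos) * 0.5
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of midranks; the p-value tests departure
#' from rho = 0 using the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (pairs with missing values are
#'   dropped); at least 4 complete pairs, neither constant.
#' @return list with \code{rho}, \code{p} and \code{n}.
#' @export
spearman <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("spearman requires at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman: constant input vector")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Fold induction of a stimulated readout over its untreated baseline
#'
#' @param stim_value stimulated readout (same subject, same analyte).
#' @param nt_value untreated (NT) readout; must be positive for a defined
#'   ratio. Non-positive baselines yield \code{NA} with a warning so the
#'   record can be dropped upstream.
#' @return \code{stim_value / nt_value}, or \code{NA} where the baseline is
#'   non-positive.
#' @export
fold_induction <- function(stim_value, nt_value) {
  out <- ifelse(is.finite(nt_value) & nt_value > 0,
                stim_value / nt_value, NA_real_)
  if (anyNA(out))
    warning(sum(is.na(out)),
            " fold-induction record(s) dropped: non-positive NT baseline")
  out
}

#' Screen functional readouts for correlation with a protein phenotype
#'
#' Computes the Spearman correlation between the per-subject phenotype and
#' every (stimulus, analyte) readout cell, plus a fold-induction variant
#' (stimulated / NT) for each cell whose analyte also has untreated (NT)
#' records. Experiment-wise significance is Bonferroni:
#' \code{p <= alpha / m} with m the number of tests actually performed in the
#' screen.
#'
#' @param phenotype data.frame with columns \code{subject_id} and
#'   \code{value}.
#' @param readouts data.frame with columns \code{subject_id},
#'   \code{stimulus}, \code{analyte}, \code{value}. The untreated stimulus is
#'   identified by \code{nt_label}.
#' @param alpha experiment-wise significance level (default 0.05).
#' @param nt_label stimulus label of the untreated baseline (default "NT").
#' @param min_pairs minimum complete pairs per cell (default 4); smaller
#'   cells are skipped with a warning.
#' @return data.frame with one row per tested cell: \code{stimulus},
#'   \code{output}, \code{n}, \code{rho}, \code{p},
#'   \code{significant_experimentwise}; sorted by p. The number of tests is
#'   attached as attribute \code{"n_tests"}.
#' @export
correlation_screen <- function(phenotype, readouts, alpha = 0.05,
                               nt_label = "NT", min_pairs = 4L) {
  stopifnot(all(c("subject_id", "value") %in% names(phenotype)),
            all(c("subject_id", "stimulus", "analyte", "value") %in%
                  names(readouts)))
  ph <- stats::setNames(phenotype$value, phenotype$subject_id)

  cells <- unique(readouts[, c("stimulus", "analyte")])
  rows <- list()
  skipped <- 0L

  get_cell <- function(stim, an) {
    r <- readouts[readouts$stimulus == stim & readouts$analyte == an, ]
    stats::setNames(r$value, r$subject_id)
  }

  add_test <- function(stim, label, vals) {
    ids <- intersect(names(ph), names(vals))
    if (length(ids) < min_pairs) {
      skipped <<- skipped + 1L
      return(invisible(NULL))
    }
    sp <- tryCatch(spearman(ph[ids], vals[ids]), error = function(e) NULL)
    if (is.null(sp)) {
      skipped <<- skipped + 1L
      return(invisible(NULL))
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      stimulus = stim, output = label, n = sp$n, rho = sp$rho, p = sp$p,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(cells))) {
    stim <- cells$stimulus[i]; an <- cells$analyte[i]
    add_test(stim, an, get_cell(stim, an))
    if (stim != nt_label) {
      nt <- get_cell(nt_label, an)
      if (length(nt)) {
        stimvals <- get_cell(stim, an)
        ids <- intersect(names(stimvals), names(nt))
        fold <- suppressWarnings(fold_induction(stimvals[ids], nt[ids]))
        fold <- fold[!is.na(fold)]
        add_test(stim, paste("fold", an), fold)
      }
    }
  }
  if (skipped > 0)
    warning(skipped, " screen cell(s) skipped (too few paired observations)")
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(structure(data.frame(), n_tests = 0L))
  m <- nrow(out)
  out$significant_experimentwise <- out$p <= alpha / m
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "n_tests") <- m
  out
}

#' Exploratory clustering of a 1-D phenotype
#'
#' K-means (best of \code{nstart} restarts per k) or UPGMA (average-linkage
#' agglomeration on absolute differences, cut at each k), over a range of
#' cluster counts; used to look for expression subgroups.
#'
#' @param values numeric vector.
#' @param method \code{"kmeans"} or \code{"upgma"}.
#' @param k_range integer vector of cluster counts to evaluate.
#' @param nstart k-means restarts (default 20).
#' @param seed optional seed making k-means deterministic.
#' @return list with per-k integer label vectors (\code{labels}, named by k),
#'   per-k within-cluster sum of squares (\code{wss}) and the \code{method}.
#' @export
cluster_phenotype <- function(values, method = c("kmeans", "upgma"),
                              k_range = 1:4, nstart = 20L, seed = NULL) {
  method <- match.arg(method)
  x <- as.numeric(values)
  if (max(k_range) > length(x)) stop("k exceeds number of observations")
  if (!is.null(seed)) set.seed(seed)
  labels <- list(); wss <- numeric(0)
  if (method == "upgma") hc <- stats::hclust(stats::dist(x), method = "average")
  for (k in k_range) {
    if (method == "kmeans") {
      if (k == 1L) {
        cl <- rep(1L, length(x))
      } else {
        cl <- stats::kmeans(x, centers = k, nstart = nstart)$cluster
      }
    } else {
      cl <- stats::cutree(hc, k = k)
    }
    labels[[as.character(k)]] <- cl
    wss[as.character(k)] <- sum(vapply(split(x, cl), function(g)
      sum((g - mean(g))^2), numeric(1)))
  }
  list(labels = labels, wss = wss, method = method)
}

#' Flag case subjects as low expressers
#'
#' A case is a "low expresser" when its value is at or below the 25th
#' percentile of the control distribution (the \code{<=} boundary is
#' inclusive). The quantile uses linear interpolation between order
#' statistics (type 7); the convention is exposed as an argument.
#'
#' @param control_values numeric vector of control phenotypes (>= 4 values).
#' @param case_values numeric vector of case phenotypes.
#' @param prob quantile defining "low" (default 0.25).
#' @param type quantile algorithm passed to [stats::quantile()] (default 7,
#'   linear interpolation).
#' @return logical vector along \code{case_values}; the threshold is attached
#'   as attribute \code{"threshold"}.
#' @export
low_expresser_flags <- function(control_values, case_values, prob = 0.25,
                                type = 7) {
  ctrl <- control_values[is.finite(control_values)]
  if (length(ctrl) < 4) stop("need at least 4 control values")
  thr <- unname(stats::quantile(ctrl, probs = prob, type = type))
  structure(case_values <= thr, threshold = thr)
}
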