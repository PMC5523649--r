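# Genotype container, exact Hardy-Weinberg QC, variant burdens and the
# unweighted genetic risk score.

#' Construct a genotype matrix with per-variant annotations
#'
#' Additive coding: 0/1/2 copies of the alternate allele, \code{NA} for a
#' missing call. Variant annotations travel with the matrix: \code{id},
#' \code{chrom}, \code{pos}, \code{ref}, \code{alt}, and the analysis fields
#' \code{gene}, \code{region_class}, \code{functional_flag}.
#'
#' @param codes integer matrix, subjects in rows, variants in columns;
#'   values in \{0, 1, 2, NA\}.
#' @param variants data.frame of per-variant annotations, one row per column
#'   of \code{codes}; must contain at least \code{id}. Missing analysis
#'   columns are filled with defaults (\code{region_class = "intergenic"},
#'   \code{functional_flag = FALSE}).
#' @param subject_ids character vector naming the rows of \code{codes}.
#' @return an object of class \code{"geno_matrix"}.
#' @export
genotype_matrix <- function(codes, variants, subject_ids = rownames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  ok <- is.na(codes) | codes %in% 0:2
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(subject_ids)) stop("subject_ids required")
  if (nrow(variants) != ncol(codes))
    stop("variants table (", nrow(variants), " rows) does not match ",
         ncol(codes), " genotype columns")
  if (anyDuplicated(variants$id)) stop("duplicated variant ids")
  if (anyDuplicated(subject_ids)) stop("duplicated subject ids")
  defaults <- list(chrom = ".", pos = NA_integer_, ref = "A", alt = "G",
                   gene = NA_character_, region_class = "intergenic",
                   functional_flag = FALSE)
  for (nm in names(defaults))
    if (is.null(variants[[nm]])) variants[[nm]] <- defaults[[nm]]
  rownames(codes) <- subject_ids
  colnames(codes) <- variants$id
  structure(list(codes = codes, variants = variants,
                 subject_ids = as.character(subject_ids)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d subjects x %d variants (%.1f%% missing)\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' Subset a genotype matrix by variant
#'
#' @param g a \code{geno_matrix}.
#' @param which logical/integer/character selector over variants.
#' @return a \code{geno_matrix} restricted to the selected variants.
#' @export
subset_variants <- function(g, which) {
  stopifnot(inherits(g, "geno_matrix"))
  if (is.character(which)) which <- match(which, g$variants$id)
  if (anyNA(which)) stop("unknown variant id in selection")
  genotype_matrix(g$codes[, which, drop = FALSE],
                  g$variants[which, , drop = FALSE], g$subject_ids)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, every heterozygote count
#' \eqn{h} compatible with them has exact probability
#' \deqn{P(h) = \frac{n!\, 2^{h}\, n_A!\, n_a!}{n_{AA}!\, h!\, n_{aa}!\,(2n)!}}
#' under Hardy-Weinberg equilibrium. The two-sided exact p-value is the sum
#' of \eqn{P(h')} over all attainable \eqn{h'} whose probability does not
#' exceed that of the observed configuration.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return exact p-value in \eqn{(0, 1]}. The full conditional distribution
#'   is attached as attribute \code{"distribution"} (data.frame of \code{h}
#'   and \code{prob}).
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotype required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  h <- seq(rare %% 2, rare, by = 2)
  logp <- lfactorial(n) + h * log(2) + lfactorial(nA) + lfactorial(na) -
    lfactorial((nA - h) / 2) - lfactorial(h) - lfactorial((na - h) / 2) -
    lfactorial(2 * n)
  prob <- exp(logp - max(logp))    # stabilized; the distribution is then
  prob <- prob / sum(prob)         # renormalized against lgamma round-off
  obs <- prob[match(n_Aa, h)]
  p <- min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
  structure(p, distribution = data.frame(h = h, prob = prob))
}

#' Hardy-Weinberg QC filter, stratified by case/control status
#'
#' The exact test is run separately within cases and within controls at every
#' variant (missing genotypes dropped per variant and stratum); a variant is
#' excluded when its exact p falls below the threshold in either stratum.
#' Both strata (plus the combined group, for reference) are reported for
#' every variant.
#'
#' @param g a \code{geno_matrix}.
#' @param subjects data.frame with \code{id} and \code{group}
#'   (\code{"case"}/\code{"control"}), covering the matrix's subjects.
#' @param threshold exclusion threshold on the exact p (default \code{1e-5}).
#' @return list with \code{kept} (the filtered \code{geno_matrix}) and
#'   \code{results} (data.frame: \code{variant_id}, \code{stratum},
#'   \code{n_AA}, \code{n_Aa}, \code{n_aa}, \code{p_exact},
#'   \code{excluded}).
#' @export
hwe_filter <- function(g, subjects, threshold = 1e-5) {
  stopifnot(inherits(g, "geno_matrix"), threshold > 0, threshold < 1)
  grp <- subjects$group[match(g$subject_ids, subjects$id)]
  if (anyNA(grp)) stop("subjects table does not cover all genotyped subjects")
  strata <- list(case = grp == "case", control = grp == "control",
                 all = rep(TRUE, length(grp)))
  res <- list()
  pmin_cc <- rep(1, ncol(g$codes))
  for (s in names(strata)) {
    sub <- g$codes[strata[[s]], , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      cj <- sub[, j]
      nAA <- sum(cj == 0L, na.rm = TRUE)
      nAa <- sum(cj == 1L, na.rm = TRUE)
      naa <- sum(cj == 2L, na.rm = TRUE)
      p <- if (nAA + nAa + naa > 0) as.numeric(hwe_exact(nAA, nAa, naa)) else NA_real_
      if (s %in% c("case", "control") && !is.na(p))
        pmin_cc[j] <- min(pmin_cc[j], p)
      res[[length(res) + 1L]] <- data.frame(
        variant_id = g$variants$id[j], stratum = s,
        n_AA = nAA, n_Aa = nAa, n_aa = naa, p_exact = p,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, res)
  excluded_ids <- g$variants$id[pmin_cc < threshold]
  results$excluded <- results$variant_id %in% excluded_ids
  keep <- !(g$variants$id %in% excluded_ids)
  list(kept = subset_variants(g, keep), results = results,
       n_excluded = sum(!keep))
}

#' Per-subject variant burden within a region or variant set
#'
#' Counts, per subject, the loci carrying at least one alternate allele among
#' the selected variants (\code{mode = "locus"}, the default) or the total
#' alternate-allele dosage (\code{mode = "dosage"}). Missing genotypes
#' contribute 0.
#'
#' @param g a \code{geno_matrix}.
#' @param select logical/integer/character variant selector, or a function of
#'   the variants annotation data.frame returning a logical (e.g.
#'   \code{function(v) v$region_class == "upstream_regulatory"}); \code{NULL}
#'   selects all variants.
#' @param mode \code{"locus"} (carrier loci) or \code{"dosage"} (allele
#'   count).
#' @param subjects optional subjects data.frame (\code{id}, \code{group});
#'   when given, per-group burden histograms are attached as attribute
#'   \code{"histogram"}.
#' @return named integer vector of per-subject burdens.
#' @export
burden_by_region <- function(g, select = NULL, mode = c("locus", "dosage"),
                             subjects = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  mode <- match.arg(mode)
  if (is.function(select)) select <- select(g$variants)
  sub <- if (is.null(select)) g else subset_variants(g, select)
  cc <- sub$codes
  cc[is.na(cc)] <- 0L
  burden <- if (mode == "locus") rowSums(cc >= 1L) else rowSums(cc)
  burden <- stats::setNames(as.integer(burden), sub$subject_ids)
  if (!is.null(subjects)) {
    grp <- subjects$group[match(sub$subject_ids, subjects$id)]
    attr(burden, "histogram") <- tapply(burden, grp, function(b)
      table(factor(b, levels = 0:max(burden))))
  }
  burden
}

#' Unweighted genetic risk score over putative functional variants
#'
#' The per-subject count of carried loci among variants flagged as putative
#' functional (regulatory motifs, non-synonymous substitutions, proximal
#' UTRs). Unweighted by design; weighting is an extension point.
#'
#' @inheritParams burden_by_region
#' @return named integer vector of per-subject scores.
#' @export
genetic_risk_score <- function(g, mode = c("locus", "dosage"),
                               subjects = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (!any(g$variants$functional_flag))
    stop("no variants with functional_flag = TRUE")
  burden_by_region(g, select = g$variants$functional_flag,
                   mode = match.arg(mode), subjects = subjects)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' \eqn{D = \sup_x |ECDF_a(x) - ECDF_b(x)|} with the asymptotic Kolmogorov
#' p-value; used to compare burden/score distributions between statuses.
#'
#' @param a,b numeric samples.
#' @return list with \code{D} and \code{p}.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}
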