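# Haplotype phasing by Gibbs sampling, variant-group assignment and
# trend/group association tests for a targeted gene region.
#
# The phaser is a minimal frequency-based Gibbs sampler: haplotype
# frequencies are estimated from the current phase assignments (with a
# symmetric pseudo-count prior) and each ambiguous subject's phase
# configuration is resampled with probability proportional to the product of
# its two haplotype frequencies. No recombination or coalescent prior is
# used; at targeted-region scale (<= 25 sites, strong LD) the simple sampler
# is adequate.

#' Phase genotypes by Gibbs sampling
#'
#' Phases are initialized uniformly at random among configurations consistent
#' with each genotype. Each sweep (a) recomputes haplotype counts from the
#' current phases and (b) resamples every subject with two or more
#' heterozygous sites with probability proportional to the product of its two
#' haplotype weights (current count plus a pseudo-count of
#' \code{pseudo_count} for any candidate haplotype). After burn-in, each
#' subject's modal configuration is reported with its posterior frequency
#' across kept sweeps, and haplotype frequencies are posterior means of the
#' per-sweep sample frequencies.
#'
#' A subject's phase configuration is enumerated exhaustively when it has at
#' most \code{max_enum_het} heterozygous sites; beyond that the sampler
#' updates one heterozygous site's phase at a time (a site-wise Gibbs scan
#' over the same target distribution).
#'
#' Missing genotypes inside the phased subset are imputed to the site's modal
#' genotype code for phasing only and flagged in the output; subjects missing
#' every site are reported without a phase.
#'
#' @param g a \code{geno_matrix} (or plain subjects-by-sites code matrix)
#'   with at most 25 sites.
#' @param n_iter total Gibbs sweeps (default 2000).
#' @param burn_in sweeps discarded before tallying (default 500).
#' @param seed integer seed; identical seed and iteration budget give
#'   identical output.
#' @param pseudo_count symmetric prior weight added to every candidate
#'   haplotype (default 1).
#' @param max_enum_het enumeration limit on heterozygous sites per subject
#'   (default 12, i.e. at most 2048 configurations).
#' @return list with \code{phases} (data.frame: \code{subject_id},
#'   \code{hap1}, \code{hap2} as 0/1 strings, \code{posterior},
#'   \code{n_het}, \code{n_imputed}), \code{frequencies} (data.frame:
#'   \code{haplotype}, \code{freq}, summing to 1), and the sampler settings.
#' @export
gibbs_phase <- function(g, n_iter = 2000L, burn_in = 500L, seed = NULL,
                        pseudo_count = 1, max_enum_het = 12L) {
  codes <- if (inherits(g, "geno_matrix")) g$codes else as.matrix(g)
  ids <- if (inherits(g, "geno_matrix")) g$subject_ids else
    (rownames(codes) %||% paste0("S", seq_len(nrow(codes))))
  m <- ncol(codes)
  if (m < 1 || m > 25) stop("gibbs_phase handles 1 to 25 sites, got ", m)
  stopifnot(n_iter > burn_in, burn_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(codes)
  pow2 <- 2^(seq_len(m) - 1)

  absent <- rowSums(is.na(codes)) == m
  if (any(absent))
    message(sum(absent), " subject(s) missing every site: phase not estimated")

  # modal-genotype imputation of missing calls (phasing only)
  imputed <- matrix(FALSE, n, m)
  work <- codes
  for (j in seq_len(m)) {
    miss <- is.na(work[, j])
    if (any(miss)) {
      obs <- work[!miss, j]
      modal <- if (length(obs)) as.integer(names(which.max(table(obs)))) else 0L
      work[miss, j] <- modal
      imputed[miss, j] <- TRUE
    }
  }

  # per-subject consistent configurations, encoded as integer haplotypes
  # (bit i = alt allele at site i); first het site fixed to hap1 = alt, which
  # halves the space and canonicalizes the unordered pair
  subj <- vector("list", n)
  for (s in seq_len(n)) {
    if (absent[s]) next
    gt <- work[s, ]
    het <- which(gt == 1L)
    base <- sum(pow2[gt == 2L])
    nh <- length(het)
    if (nh == 0L) {
      subj[[s]] <- list(h1 = base, h2 = base, nh = 0L)
    } else if (nh - 1L <= max_enum_het) {
      free <- het[-1L]
      k <- length(free)
      conf <- if (k) as.matrix(expand.grid(rep(list(0:1), k))) else
        matrix(0, 1, 0)
      h1 <- base + pow2[het[1L]] +
        (if (k) as.vector(conf %*% pow2[free]) else 0)
      h2 <- base + (if (k) as.vector((1 - conf) %*% pow2[free]) else 0)
      subj[[s]] <- list(h1 = h1, h2 = h2, nh = nh)
    } else {
      subj[[s]] <- list(het = het, base = base, nh = nh, sitewise = TRUE)
    }
  }

  # dense haplotype counts when the site space is small, hashed otherwise
  dense <- m <= 16L
  cnt <- if (dense) numeric(2^m) else new.env(hash = TRUE, parent = emptyenv())
  cget <- if (dense) function(k) cnt[k + 1] else
    function(k) vapply(as.character(k), function(kk)
      if (is.null(cnt[[kk]])) 0 else cnt[[kk]], numeric(1), USE.NAMES = FALSE)
  cadd <- if (dense) function(k, d) cnt[k + 1] <<- cnt[k + 1] + d else
    function(k, d) for (kk in as.character(k))
      cnt[[kk]] <- (if (is.null(cnt[[kk]])) 0 else cnt[[kk]]) + d

  # random initial configuration per subject
  state <- vector("list", n)     # current c(h1, h2)
  cfg_idx <- integer(n)          # current configuration index (enumerated)
  for (s in seq_len(n)) {
    sp <- subj[[s]]
    if (is.null(sp)) next
    if (is.null(sp$sitewise)) {
      i <- sample.int(length(sp$h1), 1L)
      cfg_idx[s] <- i
      state[[s]] <- c(sp$h1[i], sp$h2[i])
    } else {
      bits <- c(1L, sample(0:1, sp$nh - 1L, replace = TRUE))
      h1 <- sp$base + sum(pow2[sp$het[bits == 1L]])
      h2 <- sp$base + sum(pow2[sp$het[bits == 0L]])
      state[[s]] <- c(h1, h2)
      attr(state[[s]], "bits") <- bits
    }
    cadd(state[[s]], 1)
  }

  ambiguous <- which(!absent & vapply(subj, function(sp)
    !is.null(sp) && sp$nh >= 2L, logical(1)))
  kept <- 0L
  tally <- vector("list", n)     # per-subject config tallies
  for (s in seq_len(n)) {
    sp <- subj[[s]]
    if (is.null(sp)) next
    tally[[s]] <- if (is.null(sp$sitewise)) numeric(length(sp$h1)) else
      numeric(0)
  }
  freq_sum <- numeric(0)         # accumulated haplotype sample frequencies
  total_haps <- 2 * sum(!absent)

  for (it in seq_len(n_iter)) {
    for (s in ambiguous) {
      sp <- subj[[s]]
      cadd(state[[s]], -1)
      if (is.null(sp$sitewise)) {
        w1 <- cget(sp$h1) + pseudo_count
        w2 <- cget(sp$h2) + pseudo_count + (sp$h1 == sp$h2)
        i <- sample.int(length(w1), 1L, prob = w1 * w2)
        cfg_idx[s] <- i
        state[[s]] <- c(sp$h1[i], sp$h2[i])
      } else {
        bits <- attr(state[[s]], "bits")
        for (k in 2:sp$nh) {
          alt <- bits; alt[k] <- 1L - alt[k]
          hp <- function(b) {
            h1 <- sp$base + sum(pow2[sp$het[b == 1L]])
            h2 <- sp$base + sum(pow2[sp$het[b == 0L]])
            c(h1, h2)
          }
          cur <- hp(bits); prop <- hp(alt)
          wc <- (cget(cur[1]) + pseudo_count) *
            (cget(cur[2]) + pseudo_count + (cur[1] == cur[2]))
          wp <- (cget(prop[1]) + pseudo_count) *
            (cget(prop[2]) + pseudo_count + (prop[1] == prop[2]))
          if (stats::runif(1) < wp / (wc + wp)) bits <- alt
        }
        pair <- {
          h1 <- sp$base + sum(pow2[sp$het[bits == 1L]])
          h2 <- sp$base + sum(pow2[sp$het[bits == 0L]])
          c(h1, h2)
        }
        state[[s]] <- pair
        attr(state[[s]], "bits") <- bits
      }
      cadd(state[[s]], 1)
    }
    if (it > burn_in) {
      kept <- kept + 1L
      for (s in seq_len(n)) {
        sp <- subj[[s]]
        if (is.null(sp)) next
        if (is.null(sp$sitewise)) {
          i <- if (sp$nh >= 2L) cfg_idx[s] else 1L
          tally[[s]][i] <- tally[[s]][i] + 1
        } else {
          key <- paste(attr(state[[s]], "bits"), collapse = "")
          cur <- tally[[s]][key]
          tally[[s]][key] <- if (is.na(cur)) 1 else cur + 1
        }
      }
      keys <- unlist(lapply(which(!absent), function(s) state[[s]]))
      tab <- table(keys) / total_haps
      for (kk in names(tab)) {
        cur <- freq_sum[kk]
        freq_sum[kk] <- (if (is.na(cur)) 0 else cur) + tab[[kk]]
      }
    }
  }

  hap_string <- function(k) paste(as.integer(bitwAnd(as.integer(k %/% pow2), 1L)),
                                  collapse = "")
  phases <- do.call(rbind, lapply(seq_len(n), function(s) {
    sp <- subj[[s]]
    if (is.null(sp))
      return(data.frame(subject_id = ids[s], hap1 = NA_character_,
                        hap2 = NA_character_, posterior = NA_real_,
                        n_het = NA_integer_, n_imputed = sum(imputed[s, ]),
                        stringsAsFactors = FALSE))
    if (is.null(sp$sitewise)) {
      i <- which.max(tally[[s]])
      pair <- sort(c(hap_string(sp$h1[i]), hap_string(sp$h2[i])))
      post <- tally[[s]][i] / kept
    } else {
      key <- names(which.max(tally[[s]]))
      bits <- as.integer(strsplit(key, "")[[1]])
      h1 <- sp$base + sum(pow2[sp$het[bits == 1L]])
      h2 <- sp$base + sum(pow2[sp$het[bits == 0L]])
      pair <- sort(c(hap_string(h1), hap_string(h2)))
      post <- tally[[s]][[key]] / kept
    }
    data.frame(subject_id = ids[s], hap1 = pair[1], hap2 = pair[2],
               posterior = unname(post), n_het = sp$nh,
               n_imputed = sum(imputed[s, ]), stringsAsFactors = FALSE)
  }))

  freqs <- data.frame(haplotype = vapply(as.numeric(names(freq_sum)),
                                         hap_string, character(1)),
                      freq = unname(freq_sum) / kept,
                      stringsAsFactors = FALSE)
  freqs <- freqs[order(-freqs$freq), ]
  rownames(freqs) <- NULL
  list(phases = phases, frequencies = freqs, n_iter = n_iter,
       burn_in = burn_in, kept = kept, pseudo_count = pseudo_count)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign subjects to variant groups
#'
#' A subject carries a variant set when it has at least one alternate allele
#' at any variant in the set. Labels follow a fixed precedence: a subject
#' carrying both protective and risk variants is \code{excluded_conflict}
#' (potentially conflicting effects); otherwise \code{risk}; otherwise
#' \code{protective_plus_core} when carrying both protective and core
#' variants; otherwise \code{protective}; otherwise \code{core}; otherwise
#' \code{none}.
#'
#' @param g a \code{geno_matrix}.
#' @param group_defs named list with character vectors of variant ids for
#'   \code{core}, \code{protective} and \code{risk} (any may be empty).
#' @return data.frame with \code{subject_id} and \code{label}.
#' @export
assign_groups <- function(g, group_defs) {
  stopifnot(inherits(g, "geno_matrix"))
  for (nm in c("core", "protective", "risk"))
    if (is.null(group_defs[[nm]])) group_defs[[nm]] <- character(0)
  unknown <- setdiff(unlist(group_defs), g$variants$id)
  if (length(unknown))
    stop("unknown variant id(s) in group definitions: ",
         paste(unknown, collapse = ", "))
  carrier <- function(ids) {
    if (!length(ids)) return(rep(FALSE, nrow(g$codes)))
    cc <- g$codes[, match(ids, g$variants$id), drop = FALSE]
    cc[is.na(cc)] <- 0L
    rowSums(cc >= 1L) > 0
  }
  core <- carrier(group_defs$core)
  prot <- carrier(group_defs$protective)
  risk <- carrier(group_defs$risk)
  label <- ifelse(prot & risk, "excluded_conflict",
           ifelse(risk, "risk",
           ifelse(prot & core, "protective_plus_core",
           ifelse(prot, "protective",
           ifelse(core, "core", "none")))))
  data.frame(subject_id = g$subject_ids, label = label,
             stringsAsFactors = FALSE)
}

#' Pairwise permutation comparison of phenotype between variant groups
#'
#' Runs [permuted_mean_test()] between every pair of variant groups (or a
#' designated subset of pairs), dropping \code{excluded_conflict} subjects
#' and skipping pairs where either group has fewer than 2 members. Group
#' medians are reported alongside.
#'
#' @param labels data.frame from [assign_groups()].
#' @param phenotype named numeric vector (names = subject ids) or data.frame
#'   with \code{subject_id}, \code{value}.
#' @param pairs optional 2-column character matrix of group pairs to compare;
#'   default all pairs among the labels present.
#' @param n_perm permutations per comparison.
#' @param seed integer seed.
#' @return data.frame with one row per comparison: groups, sizes, medians,
#'   \code{p_perm}, CI bounds and the Mann-Whitney cross-check.
#' @export
group_phenotype_comparison <- function(labels, phenotype, pairs = NULL,
                                       n_perm = 10000L, seed = NULL) {
  if (is.data.frame(phenotype))
    phenotype <- stats::setNames(phenotype$value, phenotype$subject_id)
  lab <- labels[labels$label != "excluded_conflict", ]
  val <- phenotype[lab$subject_id]
  present <- names(which(table(lab$label) >= 1))
  if (is.null(pairs)) {
    if (length(present) < 2) return(data.frame())
    pairs <- t(utils::combn(sort(present), 2))
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    sel <- lab$label %in% c(g1, g2)
    v <- val[sel]; l <- lab$label[sel]
    if (sum(l == g1) < 2 || sum(l == g2) < 2 || anyNA(v)) {
      warning("comparison ", g1, " vs ", g2, " skipped (undersized group)")
      next
    }
    pt <- permuted_mean_test(v, l, n_perm = n_perm)
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = g1, group2 = g2,
      n1 = sum(l == g1), n2 = sum(l == g2),
      median1 = stats::median(v[l == g1]), median2 = stats::median(v[l == g2]),
      p_perm = pt$p_perm, ci_lo = pt$ci95[1], ci_hi = pt$ci95[2],
      p_mann_whitney = pt$p_mann_whitney, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame() else out
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in case proportion across ordered dosage
#' categories, with scores 0, 1, 2, ... by default. Two-sided p from the
#' standard normal. A table with no dosage variance returns Z = 0, p = 1.
#'
#' @param tbl 2 x k matrix of counts: rows = status (cases first), columns =
#'   ordered dosage categories.
#' @param scores column scores (default \code{0:(k-1)}).
#' @return list with \code{Z} and \code{p}.
#' @export
cochran_armitage <- function(tbl, scores = NULL) {
  tbl <- as.matrix(tbl)
  if (nrow(tbl) != 2) stop("tbl must have exactly 2 rows (status)")
  if (any(rowSums(tbl) == 0)) stop("both status rows must be nonempty")
  k <- ncol(tbl)
  s <- if (is.null(scores)) seq_len(k) - 1 else scores
  r1 <- sum(tbl[1, ]); r2 <- sum(tbl[2, ])
  cs <- colSums(tbl)
  N <- r1 + r2
  Tstat <- sum(s * (tbl[1, ] * r2 - tbl[2, ] * r1))
  cross <- sum(outer(s, s) * outer(cs, cs) * upper.tri(diag(k)))
  v <- (r1 * r2 / N) * (sum(s^2 * cs * (N - cs)) - 2 * cross)
  if (v <= 0) return(list(Z = 0, p = 1))
  Z <- Tstat / sqrt(v)
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Switch error between inferred and true phases
#'
#' Fraction of adjacent heterozygous site pairs whose inferred phase
#' relationship disagrees with the truth, pooled over subjects (subjects with
#' fewer than two heterozygous sites contribute nothing).
#'
#' @param inferred data.frame of phases as returned by [gibbs_phase()].
#' @param truth_h1,truth_h2 matrices (subjects x sites, 0/1) of true
#'   haplotypes, rows in the order of \code{inferred$subject_id}.
#' @return overall switch-error rate (switches / evaluated adjacent pairs),
#'   \code{NaN} when no subject is informative.
#' @export
switch_error <- function(inferred, truth_h1, truth_h2) {
  stopifnot(nrow(inferred) == nrow(truth_h1),
            all(dim(truth_h1) == dim(truth_h2)))
  switches <- 0L; pairs <- 0L
  for (s in seq_len(nrow(inferred))) {
    if (is.na(inferred$hap1[s])) next
    h1 <- as.integer(strsplit(inferred$hap1[s], "")[[1]])
    het <- which(truth_h1[s, ] + truth_h2[s, ] == 1L)
    if (length(het) < 2) next
    mism <- h1[het] != truth_h1[s, het]
    switches <- switches + sum(mism[-1] != mism[-length(mism)])
    pairs <- pairs + length(het) - 1L
  }
  switches / pairs
}
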