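---
title: "Statistical methods for protein-QTL and variant-group analysis in small case/control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for protein-QTL and variant-group analysis in small case/control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protqtl)
```

## The setting

`protqtl` implements the statistical machinery for a common study design in
immunogenetics: a small case/control cohort (tens of subjects per arm) with

* a quantitative protein phenotype measured in a cell lysate (an
  anti-inflammatory protein such as TNFAIP3 in macrophages, assayed by ELISA
  and normalized to total lysate protein),
* functional readouts per subject (phospho-protein and cytokine levels under
  a panel of stimuli), and
* targeted next-generation sequencing of a gene panel, yielding a few
  thousand biallelic SNVs.

At this sample size, asymptotic approximations are fragile and the analyte
distribution is strongly right-skewed, so the workflow leans on Monte-Carlo
permutation inference, an exact Hardy–Weinberg test for genotype QC, and a
Box–Cox transformation ahead of any linear modelling. Because subject-level
data of the motivating study design are typically not shareable, the package
ships a synthetic cohort generator that reproduces the statistical structure
of such a cohort; every stage of the pipeline is exercised and tested
against it.

## Phenotype normalization and transformation

The analyte value is divided by the total lysate protein concentration
(`normalize_phenotype()`), a standard correction for cell-input variability.
Normality of the resulting ratios is checked with a Shapiro–Wilk test; when
it fails (it essentially always does for lysate ratios), the ratios are
power-transformed. `boxcox_fit()` maximizes the Gaussian profile
log-likelihood

$$\ell(\lambda) = -\tfrac{n}{2}\log\hat\sigma^2_\lambda +
  (\lambda - 1)\sum_i \log y_i$$

over a grid spanning at least $[-2, 2]$ (step 0.01 by default; the grid
resolution bounds the reported $\hat\lambda$, which is ample since
downstream inference is insensitive to third-decimal changes in
$\lambda$). Zero or negative values are not silently shifted: the caller
must add an offset, and `offset_for_boxcox()` supplies the convention used
here (half the smallest positive value), which is recorded alongside
$\lambda$ as part of the transform's provenance.

## The permutation routine

Group contrasts use a pooled-variance two-sample $T$ statistic whose null
distribution is generated by uniformly re-assigning group labels
(`permuted_mean_test()`). The permuted p-value is reported exactly as the
exceedance frequency $b/B$, where $b$ counts permuted $|T| \ge |T|_{obs}$
— both directions of group difference are treated as extreme, since either
is interpretable in this design. A $(b+1)/(B+1)$ variant is emitted as a
secondary column for downstream consumers that cannot tolerate a literal
zero. Because $\hat p$ is a binomial proportion, `mc_pvalue_ci()` attaches
its normal-approximation 95% interval
$\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/B}$: at $B = 10^6$ the interval for
$p = 0.0001$ is $(0.00008, 0.00012)$, which is what justifies one million
iterations as "stable" for small p-values; the package default follows
that setting, while tests and example analyses run at $10^4$–$2\times10^4$
with the correspondingly wider interval reported alongside. A Mann–Whitney
U test (midranks; exact for tie-free groups of at most 8) accompanies every
permutation result as a rank-based cross-check.

Two degenerate-input rules are fixed deliberately: identical group means
with zero pooled variance give $T = 0$, $p = 1$; differing means with zero
pooled variance replace $|T|$ by the absolute mean difference for the
observed and every permuted assignment, keeping the test defined on
constant-within-group fixtures. For cohorts of nine or fewer subjects the
test can enumerate all label assignments (`exhaustive = TRUE`), which the
test suite holds equal to an independent enumeration oracle.

## Correlation screen and clustering

`correlation_screen()` computes Spearman's $\rho$ (Pearson correlation of
midranks, $t$ approximation with $n-2$ df for the p-value) between the
phenotype and every (stimulus, analyte) readout cell, plus a fold-induction
variant — stimulated over untreated ratio — wherever an untreated baseline
exists. Fold induction is defined as the plain ratio (not the relative
change); records with a non-positive baseline are dropped with a warning.
Experiment-wise significance is Bonferroni at $\alpha/m$ with $m$ the
number of tests actually performed in the screen, matching the package's
general multiple-testing stance: nominal p-values plus a Bonferroni flag,
no FDR.

Expression subgroups are explored with `cluster_phenotype()`: 1-D k-means
(best of 20 restarts per $k$) and UPGMA (average linkage on absolute
differences), both reported across a $k$ range with within-cluster sums of
squares — exploratory tools, not inference. "Low expressers" are cases at
or below the control 25th percentile (`low_expresser_flags()`); the
quantile uses linear interpolation between order statistics (type 7), the
boundary is inclusive, and the convention is an argument because published
analyses rarely state theirs.

## Genotype QC and burdens

`hwe_exact()` implements the exact conditional Hardy–Weinberg test:
conditioned on the observed allele counts, each attainable heterozygote
count $h$ has probability

$$P(h) = \frac{n!\, 2^{h}\, n_A!\, n_a!}{n_{AA}!\, h!\, n_{aa}!\, (2n)!},$$

and the two-sided p-value sums the probabilities not exceeding that of the
observed configuration. Probabilities are evaluated through log-factorials
and renormalized against round-off, which keeps the distribution summing to
one to $10^{-12}$ out to the sample sizes this design meets. The QC filter
(`hwe_filter()`) tests cases and controls separately and excludes a variant
when either stratum falls below the threshold (default $10^{-5}$); the
OR-across-strata rule is this package's choice where the convention is
usually left unstated. Missing genotypes are dropped per variant and
stratum.

Variant burdens (`burden_by_region()`) count loci carrying at least one
alternate allele, not allele dosage — a subject homozygous at one locus
carries one variant — because carrier counting is how such cohorts are
typically described; a dosage mode is available behind a flag. The genetic
risk score (`genetic_risk_score()`) is the unweighted burden over variants
flagged as putatively functional (regulatory motifs, non-synonymous
substitutions, proximal UTRs). It is deliberately unweighted: with tens of
subjects there is no basis for estimating per-variant weights, and
weighting is left as an extension point. Score distributions are compared
between statuses with the permutation test and a two-sample
Kolmogorov–Smirnov test (asymptotic p).

## Association scans

Case/control association (`logistic_scan()`) fits, per variant,
`status ~ genotype + age + sex` by IRLS under the additive model and reports
the Wald z for the genotype coefficient. Sex is coded 0/1 and age is
standardized before the fit (pure conditioning; the genotype coefficient is
unchanged). Monomorphic variants, non-converged fits and separated fits
(detected by runaway coefficients or standard errors) are flagged
unestimable rather than crashing a scan over thousands of variants.

The pQTL scan (`pqtl_scan()`) is the linear analogue on the transformed
phenotype, run separately for cases, controls and the combined group;
variants with fewer than five residual degrees of freedom in a stratum are
flagged. `permute_top_hits()` verifies the top $k$ (default 30) hits: the
phenotype vector is shuffled across subjects while genotypes and covariates
stay attached, the same regression is refit per permutation (vectorized
through one QR decomposition per variant, in chunks of 50,000 so the
million-permutation setting stays in memory), and the permuted p is the
$|t|$ exceedance frequency. The default shuffles the raw phenotype — the
plain exchangeability routine — with a Freedman–Lane mode (permuting
covariate-model residuals) available when covariate-respecting inference is
wanted; at the effect sizes this design cares about the two agree.

## Haplotype phasing and variant groups

`gibbs_phase()` is a minimal frequency-based Gibbs sampler for
targeted-region phasing: initialize each subject's phase uniformly among
configurations consistent with its genotype; per sweep, resample each
subject with two or more heterozygous sites proportionally to the product
of its two haplotype weights, where a weight is the current count of that
haplotype among all other subjects plus a symmetric pseudo-count (default 1
per candidate, preventing zero-frequency traps). After a burn-in (defaults
2000 sweeps, 500 burn-in) the modal configuration per subject is reported
with its posterior frequency across kept sweeps, and haplotype frequencies
are posterior means of per-sweep sample frequencies (summing to one by
construction). There is no recombination or coalescent prior: at
targeted-region scale (at most 25 sites in strong LD) the simple sampler
phases essentially perfectly, and the test suite holds it to a closed-form
two-site posterior and a 5% switch-error bound on five-site blocks. A
subject's configuration space is enumerated exhaustively up to 12
heterozygous sites ($2^{11}$ configurations); beyond that the sampler
updates one site's phase at a time, a site-wise Gibbs scan over the same
target. Missing sites are imputed to the site's modal genotype for phasing
only and flagged; subjects missing every site get no phase.

`assign_groups()` maps carrier status over named variant sets (core,
protective, risk) to a single label per subject with a fixed precedence:
protective-and-risk carriers are excluded as conflicting; otherwise risk
beats protective-plus-core beats protective beats core beats none. The
precedence for combinations not described in the motivating design is this
package's rule and is stated here so downstream counts are reproducible.
Group phenotype contrasts reuse the permutation test pairwise with group
medians reported; the trend of a haplotype's dosage across status uses the
Cochran–Armitage test (`cochran_armitage()`, scores $0,1,2$, two-sided
normal p, $p = 1$ on zero-variance tables).

## The synthetic cohort generator

`simulate_cohort()` draws two haplotypes per subject per LD block from a
specified pool, codes genotypes additively, and builds the phenotype on the
log scale:

$$\log y_i = \mu_{status(i)} + \textstyle\sum_g s_g\,[i \text{ carries set } g]
  + \beta\, G_i + \varepsilon_i,\qquad \varepsilon_i \sim N(0, \sigma_{status(i)}^2)$$

with $G_i$ the planted-pQTL allele count. Effects are planted on the log
(transformed) scale so that linear-model recovery after Box–Cox is exact;
the emitted raw value is the normalized ratio times an independent
log-normal total-protein draw. Functional readouts are tied to the latent
phenotype through a Gaussian copula on normal scores: for a target Spearman
correlation $\rho_S$ the latent Pearson correlation is
$r = 2\sin(\pi\rho_S/6)$, and the readout is a log-normal transform of
$r z + \sqrt{1-r^2}\,\epsilon$ — the simplest mechanism with a directly
controllable Spearman target, which the tests verify to $\pm 0.1$ at
$n = 1000$.

The default configuration (`default_sim_config()`) encodes the study
conditions the package is aimed at: 50 cases and 30 controls; case/control
log-medians 77.8 and 113 with log-SDs 1.07 and 1.28 (derived from the
reported means and medians of the motivating cohort under a log-normal
model); a 12-variant gene-region block whose pool carries a reference
haplotype (frequency 0.30), a core haplotype (0.45), a protective
haplotype (0.15, shift $+0.4$ on top of the core $+1.0$) and a risk
haplotype (0.10, shift $-0.9$), so that reference-haplotype and
risk-carrier subjects sit about one log-SD below protective carriers; a
putative-functional panel sized so the expected risk score is about 6,
matching the burden scale of the motivating cohort; and one planted pQTL of
1.5 case-scale log-SD per allele at MAF 0.2 in a 40-variant trans region —
a deliberately common, strong variant, since that is the regime where a
scan over a few hundred region variants should rank the causal site first.
Age is truncated normal (mean 52, SD 12, minimum 18) and sex Bernoulli
(49% male); neither influences the phenotype, so covariate adjustment is
pure conditioning in the synthetic setting.

What the generator does *not* emulate: sequencing error and missingness
structure (missingness is uniform and off by default), LD between blocks,
genotype–status dependence (case/control scans are null by construction,
so their tests are calibration tests), stimulus kinetics, or any real
biology of the readouts beyond their rank correlation with the phenotype.
Passing tests therefore demonstrate that the statistical machinery recovers
planted structure under the stated model, not that the model captures real
macrophage data.

## Numerical and design choices

* Exceedance counting uses a relative tolerance of $10^{-8}$ on $|T|$ so
  exhaustive enumeration is invariant to floating-point noise on ties.
* Every stochastic operation takes an explicit seed; the pipeline fans a
  master seed out to stages by fixed offsets, recorded in the run report,
  so identical configuration and seed reproduce byte-identical tables.
* k-means restarts (20) and the Gibbs budget (2000/500) were chosen so the
  respective recovery tests pass with margin at the package's cohort
  scale; both are configurable.
* The analyte distribution is treated as log-normal in the generator. The
  motivating data are only known to depart from Gaussian; log-normal is an
  assumption, flagged as such, chosen because it reproduces the reported
  mean/median separation with positive support.
* Test and example analyses run at reduced Monte-Carlo sizes
  ($B = 10^3$–$2\times10^4$ permutations, 100-seed recovery studies,
  10,000-subject frequency checks); these sizes are the package's choice of
  demonstration scale, with `mc_pvalue_ci()` quantifying the implied
  precision at any $B$.

## Known limitations

The logistic separation heuristic is a guard, not a diagnosis — penalized
regression would be the next step for systematically separated variants.
The Gibbs phaser has no recombination model and should not be used beyond
a single targeted region. The Bonferroni-only multiplicity stance is
faithful to the motivating design but conservative for dense scans. And
the generator's independence assumptions (blocks independent of status and
of each other) make the null calibration tests clean but idealized.
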