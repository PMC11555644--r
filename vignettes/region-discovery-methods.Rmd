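---
title: "Region-based discovery for case-control GWAS: models and methods"
author: "regionwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based discovery for case-control GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`regionwas` implements a four-stage procedure for discovering disease
risk *regions* — stretches of the genome whose SNPs are jointly
associated with a case-control phenotype even when no single variant
reaches genome-wide significance:

1. **Window screen.** A sliding-window Bayesian decision-tree scan
   produces a posterior log-odds score (PLO, base 10) per 100-kb window
   per study; windows scoring PLO ≥ 2 (posterior odds ≥ 100) in at least
   two studies of the same stratum, and beating a permutation-null 95th
   percentile, become candidate regions.
2. **Region association test.** Each candidate is tested in each study
   with the generalized Berk–Jones (GBJ) statistic on covariate-adjusted
   per-SNP score statistics after LD pruning; candidates need GBJ
   p < 0.05 in the same studies that flagged them in stage 1.
3. **Validation.** Surviving candidates are re-tested in a held-out
   study available only as per-SNP summary statistics, with LD taken
   from a reference genotype panel.
4. **Meta-analysis.** Per-SNP effects are combined across all studies by
   a sample-size-weighted Z (Stouffer) fixed-effects model; sex-specific
   candidates get a female-minus-male effect-size contrast; Bonferroni
   ledgers are applied per region and per SNP.

A multi-study synthetic-data generator with haplotype-block LD makes
every stage testable without access to restricted genotype data.

# The window screen

## Model

For a window with dosage submatrix $G$ and phenotype $y \in \{0,1\}^n$,
the screen fits a Bayesian classification tree. Leaves carry
Beta(1,1)–Binomial marginals of the case count: a leaf with $n_1$ cases
and $n_0$ controls contributes $\log B(n_1{+}1, n_0{+}1)$. Candidate
splits have the form "dosage of SNP $j$ ≤ c" for $c \in \{0, 1\}$
(missing dosages mean-imputed); growth is greedy and a split is accepted
only when the children's summed log marginal plus a structural log-prior
of $-\ln 2$ per split exceeds the leaf marginal. Depth is capped at 3
and leaves must keep ≥ 25 samples.

The screen statistic is

$$\mathrm{PLO} = \log_{10}\frac{m(y \mid \text{tree})}{m(y \mid
\text{intercept only})},$$

the base-10 log Bayes factor against the no-association model. With
prior odds 1 this is the posterior log-odds that the window contains at
least one associated SNP: PLO = 2 means posterior odds 100. A window
with no accepted split has PLO exactly 0.

## Null gating

The null distribution is approximated by phenotype-label permutation
(which preserves the case:control ratio exactly); 1,000 permutations per
window and the type-7 95th percentile are the defaults. On null
synthetic studies at a realistic marker density (~1 SNP per 3 kb, so
~33 SNPs per 100-kb window, n ≈ 2,000–4,000) the permutation 95th
percentile sits near PLO 1 — far below the PLO ≥ 2 selection gate —
which is the calibration anchor the screen is designed around. At much
higher marker densities the flat per-split prior admits more spurious
splits and the null percentile rises; the prior penalty is configurable
via `treePrior()` if a denser panel needs a stiffer structural prior.

Two assumptions are worth making explicit: the permutation null is a
label-exchangeability null (it does not preserve confounding between
phenotype and covariates — the screen is deliberately covariate-free
and used only to *generate* hypotheses), and the
X chromosome is excluded in combined-sex strata because the tree does
not model the male/female dosage difference.

# The GBJ region test

## Marginal scores

For a region, the null logistic model `phenotype ~ covariates` (age, sex
where applicable, and optionally principal components) is fitted once.
Each SNP's score statistic for entering the model is standardized to a
z value; with no covariates this is exactly the Cochran–Armitage trend
test (asserted against a closed-form oracle in the tests). The null
correlation matrix of the scores is the weighted correlation of the
covariate-residualized dosages under the null variance function — not
the raw LD matrix — which is what makes the null draws exchangeable with
the observed vector.

## The statistic

Order the absolute scores $|z|_{(1)} \ge \dots \ge |z|_{(d)}$. At each
threshold $t_k = |z|_{(k)} > 1$, the observed exceedance count is $k$
and its null law has mean $\mu_k = d\,p_k$ with $p_k = 2\Phi(-t_k)$ and
variance

$$\sigma_k^2 = d\,p_k(1-p_k) + \sum_{i \ne j}
\left[P(|Z_i| \ge t_k, |Z_j| \ge t_k \mid \rho_{ij}) - p_k^2\right],$$

with the pairwise orthant probabilities computed from the bivariate
normal by a one-dimensional Plackett-identity quadrature. The count is
modelled by an extended beta-binomial matched to $(\mu_k, \sigma_k^2)$,
and GBJ is the maximum over qualifying $k$ of the generalized
log-likelihood ratio of $k$ exceedances against that null (0 when no
threshold shows a surplus). With an identity correlation matrix the
construction reduces — exactly, not approximately — to the classic
Berk–Jones binomial log-likelihood ratio, and with $d = 1$ the p-value
reduces to the two-sided normal p; both reductions are pinned by tests.

## P-values

P-values are Monte Carlo: `n_mc` draws from the null multivariate normal
(eigenvalue-clipped for PSD repair; clip mass reported), with the
add-one correction $p = (1 + \#\{\text{draws} \ge s\})/(n_{mc}+1)$, so
p ≥ 1/(n_mc+1) by construction. An analytic boundary-crossing
computation exists in the literature; it is deliberately not
implemented — the Monte-Carlo path is the default and its correctness
does not depend on delicate tail numerics. For many regions sharing one
correlation matrix the null statistics can be computed once and reused
(`gbjStatBatch`, `null_stats` argument of `gbjPvalue`).

## Summary-statistics mode

Stage 3 runs the same machinery with $z = \beta/\mathrm{se}$ from a
summary table and correlation from a reference panel, after aligning
each row's effect allele to the reference (swapped alleles flip the
sign; unmatched alleles drop the row, counted). A reference whose LD
differs from the source population miscalibrates the test — A/T and C/G
(strand-ambiguous) variants are therefore flagged on input and the
mismatch is observable rather than silently hidden.

# Meta-analysis and sex differences

Per-SNP per-study results are combined as
$z_{meta} = \sum_i \sqrt{w_i}\, z_i / \sqrt{\sum_i w_i}$ with
$z_i = \mathrm{sign}_i\,\Phi^{-1}(1 - p_i/2)$. The default weight is the
*effective* sample size $w = 4/(1/N_{case} + 1/N_{ctrl})$; total-N
weighting is available, but reconstructing the published meta p-values
for the two anchor SNPs from their printed per-study inputs shows
effective-N fits markedly better (a test asserts the comparison), so it
is the default. The sex-difference statistic is
$\beta_F - \beta_M$ over $\sqrt{se_F^2 + se_M^2}$ with a two-sided
normal p; when used at the pipeline level the per-sex estimates are
first pooled across studies by inverse variance.

`betaFromOrCi()` recovers $(\beta, se)$ from printed OR and 95% CI
columns; with two-decimal rounding of the OR/CI this reconstructs
printed p-values to about $|\Delta z| \le 0.05$ for clearly non-null
rows and ~0.1–0.15 near the null, which is the tolerance the tests use.

# The synthetic-data generator

`buildHaplotypePool()` produces binary haplotypes by a within-block
copying process: each new haplotype copies a random earlier one with a
per-SNP mutation rate (default 0.01) and re-chooses its template at
block boundaries with the recombination probability. This yields
block-structured LD — the only feature of real haplotypes the
downstream statistics consume — without a coalescent simulator's cost.
Defaults: 20-SNP blocks at 3 kb spacing (60-kb LD blocks, a typical
genotyping-array density), allele frequencies in [0.05, 0.95].

`simulateStudy()` draws diploid genotypes (two pool haplotypes with
replacement) and assigns case status from the logistic model
$\mathrm{logit}\,P(\text{case}) = \mathrm{logit}(p_0) + \sum_j \ln
(\mathrm{OR}_j)\, g_j$, with effects active only in the permitted sex
for sex-restricted specifications; rejection sampling runs until the
exact case/control quotas are met. Ages are normal per phenotype,
missingness is completely at random, and a per-study re-mutation rate
(`maf_jitter`) emulates between-study frequency heterogeneity. Because
the generating model is the analysis model, logistic regression is an
*exact* parameter-recovery oracle — the tests exploit this.

What the generator does **not** emulate: population admixture beyond a
two-cluster construction used in the PCA tests, genotyping batch
effects, imputation uncertainty, non-random missingness, and realistic
genome-scale LD complexity. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under the stated model,
not that real-data confounding is handled beyond the covariate and QC
machinery provided.

# Quality control and population structure

Samples are filtered before SNPs (call rates are computed on retained
samples): per-sample call rate ≥ 0.95 and complete phenotype/sex. SNP
filters, in order and each strict: call rate < 0.95, differential
case-control missingness (two-sided Fisher, p < 1e-5), MAF < 0.01, and
exact Hardy–Weinberg p < 1e-5 in controls — evaluated in all controls
and within male-only and female-only controls. The HWE test is the
exact conditional-on-allele-counts enumeration (well-defined at low
counts); the filter order and the exact-vs-asymptotic choice are
documented conventions, not claims about any particular study's
pipeline. The report charges each SNP to the first rule it fails, so
removed + retained reconciles per filter.

Relatedness is method-of-moments IBD from IBS counts and allele
frequencies; pairs above pi-hat 0.1875 (the second/third-degree
midpoint) are resolved by removing the sample in the most flagged
pairs, ties by lower call rate. PCA mean-imputes missing dosages (PCA
only), standardizes by $\sqrt{2p(1-p)}$, and takes the top-k singular
structure — full SVD for small matrices, randomized subspace iteration
(fixed internal seed, caller RNG untouched) for large ones. Ancestry
outliers are a deterministic surrogate for visual reference-cluster
inspection: robust z > 6 on PC1/PC2 against a reference subset, with an
SD fallback when the MAD degenerates.

# Numerical and design choices

* Dosage is an integer alphabet {0, 1, 2, NA}; NA is never imputed
  except where a method documents it (tree splits, score statistics,
  PCA, LD pruning — all mean-imputation, genotypes untouched).
* LD pruning is greedy and windowed (50 SNPs, step 5, r² > 0.5 removes
  the lower-MAF member, ties to the later position), matching a
  brute-force full-matrix oracle on block-sized windows.
* Ties and sign conventions: PC score columns have their
  largest-magnitude entry positive; boot percentiles are type-7
  quantiles; the GBJ threshold set is restricted to $|z| > 1$.
* Monte-Carlo p-values never return 0; p = 0 inputs to the meta are
  clipped to the smallest representable double with a warning.
* All stochastic stages require explicit seeds; pipeline stages derive
  per-task seeds from the single config seed, so a full run replays
  byte-identically.

# Validation problem sizes

The test suite and the acceptance script exercise the method at desk
scale, chosen to keep full runs reproducible on one CPU: GBJ
calibration at d = 50, exchangeable ρ = 0.3, 2,000 null replicates
against a 20,000-draw Monte-Carlo null; screen calibration on a null
study of 1,000 cases/1,000 controls across ~140 windows with 400
permutations each; end-to-end recovery on three parallel studies of
2,000 cases/2,000 controls over a 7.5-Mb, 2,500-SNP genome with one
100-kb region carrying three common causal variants at OR 1.3 (the
planted region must survive stages 1–2 in at least half of 20
replicates, while null genomes are monitored for false candidates); and
sex-difference detection at a male-only OR 1.3 variant with n = 4,000.

# Known limitations

* The screen's tree model is a documented surrogate: it reproduces the
  published interface (base-10 PLO, prior odds 1, permutation null near
  PLO 1) with fully specified internals, not any particular external
  implementation.
* GBJ p-values are Monte Carlo; extremely small region p-values are
  bounded below by 1/(n_mc+1).
* The aggregated-data mode (study indicator as covariate) is available
  by concatenating studies and passing the indicator in the covariate
  matrix, but the pipeline never uses pooled data for discovery.
* Strata are sex-based in the shipped pipeline; disease-subtype strata
  slot in as additional sample filters but have no dedicated
  bookkeeping beyond the stratum label.
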