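## Multi-study case-control genotype simulator.
##
## Haplotypes come from a within-block copying process (each new haplotype
## copies a randomly chosen earlier one with a small per-SNP mutation rate,
## and re-chooses its template independently at block boundaries), which
## produces block-structured LD without the cost of a coalescent simulator:
## the statistics tested downstream depend on the genotype correlation
## structure, not on genealogy.  Disease status follows the same logistic
## model the analysis stages fit, so parameter recovery is an exact oracle.

#' Build a haplotype pool with LD-block structure
#'
#' @param n_hap number of haplotypes (>= 100)
#' @param n_snp number of SNPs
#' @param block_len SNPs per LD block
#' @param recomb_between_blocks probability (0, 0.5] that a haplotype
#'   switches to a fresh random template at each block boundary; 0.5 with
#'   \code{mutation = 0.5} yields independent SNPs
#' @param maf_range allowed interval for realized allele-1 frequencies
#'   (default c(0.05, 0.95)); SNPs outside it after generation are repaired
#'   by random toggling, with a bounded retry budget
#' @param mutation per-SNP copy-error probability (default 0.01)
#' @param bp_per_snp base-pair spacing between adjacent SNPs (default 3000,
#'   a typical genotyping-array density)
#' @param chrom chromosome label (default "1")
#' @param seed integer seed; the pool is a pure function of the arguments
#' @return a \linkS4class{HaplotypePool}
#' @export
buildHaplotypePool <- function(n_hap, n_snp, block_len = 20,
                               recomb_between_blocks = 0.1,
                               maf_range = c(0.05, 0.95),
                               mutation = 0.01, bp_per_snp = 3000L,
                               chrom = "1", seed) {
  stopifnot(n_hap >= 100, n_snp >= 1,
            recomb_between_blocks > 0, recomb_between_blocks <= 0.5,
            maf_range[1] > 0, maf_range[2] < 1,
            maf_range[1] < maf_range[2])
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  blocks <- rep(seq_len(ceiling(n_snp / block_len)),
                each = block_len)[seq_len(n_snp)]
  base_f <- runif(n_snp, maf_range[1], maf_range[2])
  H <- matrix(0L, nrow = n_hap, ncol = n_snp)
  H[1, ] <- rbinom(n_snp, 1L, base_f)
  n_block <- max(blocks)
  for (h in 2:n_hap) {
    ## template per block: switch with prob recomb at each boundary
    tmpl <- integer(n_block)
    tmpl[1] <- sample.int(h - 1L, 1L)
    if (n_block > 1) {
      for (b in 2:n_block) {
        tmpl[b] <- if (runif(1) < recomb_between_blocks)
          sample.int(h - 1L, 1L) else tmpl[b - 1L]
      }
    }
    row <- H[cbind(tmpl[blocks], seq_len(n_snp))]
    flip <- runif(n_snp) < mutation
    row[flip] <- 1L - row[flip]
    H[h, ] <- row
  }
  ## repair SNPs whose realized frequency drifted out of range: toggle
  ## random entries toward the nearer bound (bounded retries)
  f <- colMeans(H)
  for (tries in 1:20) {
    low <- which(f < maf_range[1])
    high <- which(f > maf_range[2])
    if (!length(low) && !length(high)) break
    for (j in low) {
      k <- ceiling((maf_range[1] - f[j]) * n_hap) + 1L
      zeros <- which(H[, j] == 0L)
      H[sample(zeros, min(k, length(zeros))), j] <- 1L
    }
    for (j in high) {
      k <- ceiling((f[j] - maf_range[2]) * n_hap) + 1L
      ones <- which(H[, j] == 1L)
      H[sample(ones, min(k, length(ones))), j] <- 0L
    }
    f <- colMeans(H)
  }
  if (any(f < maf_range[1] | f > maf_range[2]))
    stop("could not realize MAFs inside maf_range after bounded retries")
  new("HaplotypePool", haplotypes = H, blocks = as.integer(blocks),
      maf = f, pos = as.integer(seq_len(n_snp)) * as.integer(bp_per_snp),
      chrom = chrom)
}

#' Specify a causal-region effect
#'
#' @param region single-range \link[GenomicRanges]{GRanges} (see
#'   [region()])
#' @param causal_ids variant ids carrying the effect (must lie in region)
#' @param or_per_allele odds ratio per effect-allele copy (> 0), recycled
#'   over \code{causal_ids}
#' @param sex_restriction "both", "male_only" or "female_only": the sex in
#'   which the effect is active
#' @return an \code{effect_spec} list
#' @export
effectSpec <- function(region, causal_ids, or_per_allele = 1.3,
                       sex_restriction = c("both", "male_only",
                                           "female_only")) {
  stopifnot(all(or_per_allele > 0))
  sex_restriction <- match.arg(sex_restriction)
  structure(list(region = region, causal_ids = causal_ids,
                 or_per_allele = rep_len(or_per_allele,
                                         length(causal_ids)),
                 sex_restriction = sex_restriction),
            class = "effect_spec")
}

## variant ids for a pool (stable across studies sharing the pool)
.poolVids <- function(pool) sprintf("snp%06d", seq_along(pool@maf))

#' Simulate one case-control study from a haplotype pool
#'
#' Diploid genotypes are two haplotypes drawn with replacement from the
#' pool.  Disease status follows the logistic model
#' \code{logit P(case) = logit(base_prev) + sum_j log(OR_j) g_j}, where the
#' sum runs over causal SNPs whose \code{sex_restriction} admits the
#' individual's sex.  Individuals are drawn and assigned by Bernoulli
#' sampling until the exact case and control quotas are met (rejection
#' sampling); ages come from per-phenotype normal models, and genotype
#' calls are masked missing completely at random.
#'
#' @param pool a \linkS4class{HaplotypePool}
#' @param n_case,n_ctrl required group sizes
#' @param effects list of [effectSpec()] objects (empty list = null model)
#' @param base_prev baseline case probability for a zero-dosage individual
#'   (default 0.3: keeps rejection sampling cheap in a balanced design)
#' @param age_model list with elements \code{case} and \code{control}, each
#'   \code{c(mean, sd)} in years
#' @param missing_rate per-call missing probability (default 0)
#' @param maf_jitter per-study allele-frequency perturbation: each SNP is
#'   re-mutated at this rate in the sampled genotypes, emulating the
#'   between-study frequency heterogeneity seen in real multi-study data
#'   (default 0)
#' @param p_male probability a sample is male (default 0.5)
#' @param study study label recorded per sample
#' @param seed integer seed
#' @param max_draws rejection-sampling budget as a multiple of
#'   \code{n_case + n_ctrl} (default 50)
#' @return a \linkS4class{StudyGenotypes}; causal variant ids are attached
#'   as attribute \code{"truth"} (data.frame vid, log_or, sex_restriction)
#' @export
simulateStudy <- function(pool, n_case, n_ctrl, effects = list(),
                          base_prev = 0.3,
                          age_model = list(case = c(55, 15),
                                           control = c(56, 15)),
                          missing_rate = 0, maf_jitter = 0, p_male = 0.5,
                          study = "study1", seed, max_draws = 50) {
  stopifnot(n_case >= 1, n_ctrl >= 1)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  H <- pool@haplotypes
  m <- ncol(H)
  vids <- .poolVids(pool)
  ## per-sex linear predictors over causal SNPs
  beta_m <- beta_f <- numeric(m)
  truth <- data.frame(vid = character(), log_or = numeric(),
                      sex_restriction = character())
  for (ef in effects) {
    j <- match(ef$causal_ids, vids)
    if (anyNA(j)) stop("causal id(s) not in pool: ",
                       paste(ef$causal_ids[is.na(j)], collapse = ", "))
    lo <- log(ef$or_per_allele)
    if (ef$sex_restriction %in% c("both", "male_only"))
      beta_m[j] <- beta_m[j] + lo
    if (ef$sex_restriction %in% c("both", "female_only"))
      beta_f[j] <- beta_f[j] + lo
    truth <- rbind(truth, data.frame(vid = ef$causal_ids, log_or = lo,
                                     sex_restriction = ef$sex_restriction))
  }
  a0 <- qlogis(base_prev)
  need <- c(case = n_case, control = n_ctrl)
  got <- c(case = 0L, control = 0L)
  G_keep <- matrix(0L, nrow = n_case + n_ctrl, ncol = m)
  ph <- sex <- character(n_case + n_ctrl)
  kept <- 0L
  budget <- max_draws * (n_case + n_ctrl)
  drawn <- 0L
  batch <- max(256L, n_case + n_ctrl)
  cj <- which(beta_m != 0 | beta_f != 0)
  while (any(got < need) && drawn < budget) {
    nb <- min(batch, budget - drawn)
    drawn <- drawn + nb
    i1 <- sample.int(nrow(H), nb, replace = TRUE)
    i2 <- sample.int(nrow(H), nb, replace = TRUE)
    g_c <- H[i1, cj, drop = FALSE] + H[i2, cj, drop = FALSE]
    sx <- ifelse(runif(nb) < p_male, "male", "female")
    eta <- a0 +
      ifelse(sx == "male",
             as.numeric(g_c %*% beta_m[cj]),
             as.numeric(g_c %*% beta_f[cj]))
    is_case <- runif(nb) < plogis(eta)
    take_case <- head(which(is_case), need["case"] - got["case"])
    take_ctrl <- head(which(!is_case), need["control"] - got["control"])
    take <- c(take_case, take_ctrl)
    if (length(take)) {
      rows <- kept + seq_along(take)
      G_keep[rows, ] <- H[i1[take], , drop = FALSE] +
        H[i2[take], , drop = FALSE]
      ph[rows] <- rep(c("case", "control"),
                      c(length(take_case), length(take_ctrl)))
      sex[rows] <- sx[take]
      kept <- kept + length(take)
      got["case"] <- got["case"] + length(take_case)
      got["control"] <- got["control"] + length(take_ctrl)
    }
  }
  if (any(got < need))
    stop("could not reach requested case/control counts within the ",
         "rejection-sampling budget; raise max_draws or base_prev")
  if (maf_jitter > 0) {
    ## re-mutate alleles at a small per-allele rate: each of the two
    ## haplotype copies flips independently
    for (cp in 1:2) {
      flip <- matrix(runif(length(G_keep)) < maf_jitter, nrow = nrow(G_keep))
      has <- G_keep >= cp
      G_keep[flip & has] <- G_keep[flip & has] - 1L
      G_keep[flip & !has] <- G_keep[flip & !has] + 1L
    }
    G_keep[G_keep > 2L] <- 2L
    G_keep[G_keep < 0L] <- 0L
  }
  if (missing_rate > 0)
    G_keep[matrix(runif(length(G_keep)) < missing_rate,
                  nrow = nrow(G_keep))] <- NA_integer_
  am <- rbind(case = age_model$case, control = age_model$control)
  age <- pmax(18, rnorm(kept, am[ph, 1], am[ph, 2]))
  samples <- data.frame(
    sid = sprintf("%s_s%05d", study, seq_len(kept)),
    phenotype = ph, sex = sex, age = age, study = study,
    stringsAsFactors = FALSE)
  variants <- data.frame(chrom = pool@chrom, pos = pool@pos, vid = vids,
                         a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  sg <- StudyGenotypes(dosage = G_keep, variants = variants,
                       samples = samples)
  attr(sg, "truth") <- truth
  sg
}

#' Simulate a held-out study available only as summary statistics
#'
#' Simulates a genotype study internally, runs per-SNP covariate-adjusted
#' logistic regression (sex + age), and returns only the per-SNP summary
#' table; the genotypes are discarded, mirroring a validation study for
#' which individual-level data cannot be shared.
#'
#' @inheritParams simulateStudy
#' @param ... further arguments passed to [simulateStudy()]
#' @return data.frame in the [readSummaryStats()] layout
#' @export
emitSummaryStudy <- function(pool, n_case, n_ctrl, effects = list(), seed,
                             ...) {
  sg <- simulateStudy(pool, n_case, n_ctrl, effects = effects, seed = seed,
                      ...)
  si <- sampleInfo(sg)
  vi <- variantInfo(sg)
  y <- as.integer(si$phenotype == "case")
  X <- cbind(1, male = as.integer(si$sex == "male"), age = si$age)
  G <- dosage(sg)
  out <- data.frame(chrom = vi$chrom, pos = vi$pos, vid = vi$vid,
                    a1 = vi$a1, a2 = vi$a2,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    n_case = n_case, n_ctrl = n_ctrl,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    keep <- !is.na(g)
    fit <- tryCatch(
      glm.fit(cbind(X[keep, , drop = FALSE], g = g[keep]), y[keep],
              family = binomial()),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    cf <- fit$coefficients["g"]
    ## Wald SE from the inverse Fisher information of the converged fit
    Xg <- cbind(X[keep, , drop = FALSE], g = g[keep])
    w <- fit$weights
    V <- tryCatch(solve(crossprod(Xg * sqrt(w))), error = function(e) NULL)
    if (is.null(V)) next
    se <- sqrt(V["g", "g"])
    out$beta[j] <- cf
    out$se[j] <- se
    out$p[j] <- 2 * pnorm(abs(cf / se), lower.tail = FALSE)
  }
  out[!is.na(out$beta), , drop = FALSE]
}

#' Draw from a zero-mean multivariate normal with given correlation
#'
#' The null sampler behind Monte-Carlo GBJ p-values.  \code{sigma} is
#' eigendecomposed once; eigenvalues below zero are clipped to zero (PSD
#' repair) and the total clipped mass is reported via a message and in
#' attribute \code{"clipped"}.
#'
#' @param sigma symmetric positive semi-definite matrix with unit diagonal
#' @param n_draws number of rows to draw
#' @param seed integer seed
#' @return \code{n_draws} x \code{d} matrix, attribute \code{"clipped"}
#' @export
nullZSampler <- function(sigma, n_draws, seed) {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma))
    stop("sigma must be a square matrix")
  if (max(abs(sigma - t(sigma))) > 1e-8)
    stop("sigma must be symmetric")
  if (missing(seed)) stop("seed is mandatory")
  d <- nrow(sigma)
  ee <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  clipped <- sum(pmin(ee$values, 0))
  if (clipped < -1e-8)
    message(sprintf("PSD repair: clipped eigenvalue mass %.3g", clipped))
  lam <- pmax(ee$values, 0)
  A <- ee$vectors %*% (t(ee$vectors) * sqrt(lam))
  set.seed(seed)
  Z <- matrix(rnorm(n_draws * d), nrow = n_draws) %*% A
  attr(Z, "clipped") <- clipped
  Z
}
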