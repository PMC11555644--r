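## Stage 2/3: covariate-adjusted marginal score statistics and the
## generalized Berk-Jones (GBJ) region test.
##
## The GBJ statistic screens the ordered absolute per-SNP z statistics:
## at each threshold t_k = |z|_(k) (k-th largest, restricted to t_k > 1)
## the observed exceedance count k is compared with its null law.  Under
## the null the count has mean d p_k (p_k = 2 Phi(-t_k)) and a variance
## inflated by the pairwise dependence of the z's, computed from
## bivariate-normal orthant probabilities; the count is modelled by an
## extended beta-binomial matched to that mean and variance, and GBJ is
## the maximum over thresholds of the generalized log-likelihood ratio of
## the observed count against the matched null.  With an identity
## correlation matrix the construction collapses to the classic
## Berk-Jones binomial log-likelihood ratio.

## ---- bivariate normal orthant machinery -------------------------------

## Gauss-Legendre nodes/weights on [0, 1] (used for the Plackett identity
## integral d/drho Phi2 = phi2)
.glNodes <- local({
  gl <- NULL
  function(n = 48) {
    if (is.null(gl)) {
      ## Golub-Welsch via symmetric tridiagonal eigenproblem on [-1, 1]
      i <- seq_len(n - 1)
      b <- i / sqrt(4 * i^2 - 1)
      ee <- eigen(diag(0, n) + rbind(cbind(0, diag(b)), 0) +
                    t(rbind(cbind(0, diag(b)), 0)), symmetric = TRUE)
      x <- ee$values
      w <- 2 * ee$vectors[1, ]^2
      gl <<- list(x = (x + 1) / 2, w = w / 2)   # map to [0, 1]
    }
    gl
  }
})

#' Two-sided bivariate-normal orthant probability
#'
#' \code{P(|X| >= t, |Y| >= t)} for standard bivariate normal (X, Y) with
#' correlation \code{rho}; vectorized over \code{rho}.  Uses the Plackett
#' identity to reduce the probability to a one-dimensional integral in the
#' correlation, evaluated by Gauss-Legendre quadrature.
#'
#' @param t positive threshold (scalar)
#' @param rho correlation vector in [-1, 1]
#' @return vector of orthant probabilities
#' @export
bvnOrthantBoth <- function(t, rho) {
  stopifnot(t >= 0)
  p1 <- pnorm(-t)
  ar <- pmin(abs(rho), 1 - 1e-12)
  gl <- .glNodes()
  ## integrand difference f(r) - f(-r), r in (0, |rho|)
  r <- outer(ar, gl$x)                     # n x nodes
  f <- function(rr) exp(-t^2 / (1 + rr)) / (2 * pi * sqrt(1 - rr^2))
  I <- as.numeric((f(r) - f(-r)) %*% gl$w) * ar
  ## q(t, rho) + q(t, -rho) = 2 p1^2 + I; both-tails orthant = 2 * that
  out <- 2 * (2 * p1^2 + I)
  ## exact limit for |rho| ~ 1: |Y| = |X|, so the event is |X| >= t
  out[abs(rho) > 1 - 1e-12] <- 2 * p1
  out
}

## Sum over ordered pairs (i != j) of [P(|Zi|>=t, |Zj|>=t) - p(t)^2] as a
## smooth function of t, precomputed on a grid and splined.  This is the
## correlation correction to the null exceedance-count variance.
.pairSumFun <- function(sigma, tmin = 0.99, tmax = 8.6, step = 0.05) {
  d <- nrow(sigma)
  if (d < 2) return(function(t) rep(0, length(t)))
  rho <- sigma[upper.tri(sigma)]
  tgrid <- seq(tmin, tmax, by = step)
  vals <- vapply(tgrid, function(t) {
    p <- 2 * pnorm(-t)
    2 * sum(bvnOrthantBoth(t, rho) - p^2)
  }, numeric(1))
  sf <- stats::splinefun(tgrid, vals, method = "natural")
  function(t) pmax(sf(pmin(pmax(t, tmin), tmax)), 0)
}

## ---- extended beta-binomial GLR ---------------------------------------

## GBJ_k for exceedance count k at threshold with tail prob p, overdispersion
## gamma (vectorized over draws: p, gamma vectors; k, d scalars)
.ebbGlr <- function(k, d, p, gamma) {
  out <- numeric(length(p))
  kh <- k / d
  active <- kh > p
  if (!any(active)) return(out)
  g <- gamma[active]; pa <- p[active]
  acc <- numeric(sum(active))
  if (k >= 1) for (j in 0:(k - 1))
    acc <- acc + log(kh + g * j) - log(pa + g * j)
  if (d - k >= 1) for (j in 0:(d - k - 1))
    acc <- acc + log(1 - kh + g * j) - log(1 - pa + g * j)
  out[active] <- acc
  out
}

## overdispersion parameter from matched variance
.ebbGamma <- function(var, d, p) {
  if (d == 1) return(rep(0, length(p)))
  base <- d * p * (1 - p)
  rho <- (var / base - 1) / (d - 1)
  rho <- pmin(pmax(rho, 0), 0.999)
  rho / (1 - rho)
}

## core batch evaluation: Z is n x d (rows = z vectors); pairsum is the
## precomputed variance-correction function of t
.gbjBatch <- function(Z, pairsum) {
  n <- nrow(Z); d <- ncol(Z)
  A <- abs(Z)
  Tm <- if (d == 1) A else
    t(apply(A, 1, sort, decreasing = TRUE, method = "quick"))
  stat <- numeric(n)
  for (k in seq_len(d)) {
    tk <- Tm[, k]
    ok <- tk > 1
    if (!any(ok)) next
    p <- 2 * pnorm(-tk[ok])
    v <- d * p * (1 - p) + pairsum(tk[ok])
    gam <- .ebbGamma(v, d, p)
    glr <- .ebbGlr(k, d, p, gam)
    stat[ok] <- pmax(stat[ok], glr)
  }
  stat
}

#' Generalized Berk-Jones statistic
#'
#' @param scores a list with elements \code{z} (per-SNP z statistics) and
#'   \code{sigma} (their null correlation matrix), as produced by
#'   [marginalScores()]; a plain numeric vector is accepted for
#'   independent z's
#' @param sigma correlation matrix when \code{scores} is a plain vector
#' @return the GBJ statistic (non-negative; 0 when no threshold above
#'   |z| = 1 shows an exceedance surplus)
#' @export
gbjStatistic <- function(scores, sigma = NULL) {
  if (is.list(scores)) { z <- scores$z; sigma <- scores$sigma }
  else z <- scores
  d <- length(z)
  stopifnot(d >= 1)
  if (is.null(sigma)) sigma <- diag(d)
  stopifnot(nrow(sigma) == d)
  ps <- .pairSumFun(sigma)
  .gbjBatch(matrix(z, nrow = 1), ps)
}

#' Monte-Carlo p-value for the GBJ statistic
#'
#' Draws \code{n_mc} null z vectors from a zero-mean multivariate normal
#' with correlation \code{sigma} ([nullZSampler()]), evaluates the GBJ
#' statistic on each, and returns the add-one-corrected exceedance
#' fraction \code{(1 + #\{draws >= stat\}) / (n_mc + 1)} — so p-values
#' are never smaller than \code{1/(n_mc + 1)}.
#'
#' @param stat observed statistic from [gbjStatistic()]
#' @param sigma the same correlation matrix
#' @param n_mc Monte-Carlo draws (default 20000; below 1000 warns, below
#'   100 refuses)
#' @param seed integer seed
#' @param null_stats optional precomputed null statistics (recycled across
#'   regions sharing sigma)
#' @return list(p, n_mc, null_stats)
#' @export
gbjPvalue <- function(stat, sigma, n_mc = 20000, seed,
                      null_stats = NULL) {
  if (is.null(null_stats)) {
    if (n_mc < 100) stop("n_mc below 100: refusing")
    if (n_mc < 1000) warning("n_mc below 1000: p-value resolution poor")
    Z <- nullZSampler(sigma, n_mc, seed = seed)
    ps <- .pairSumFun(sigma)
    null_stats <- .gbjBatch(Z, ps)
  }
  p <- (1 + sum(null_stats >= stat)) / (length(null_stats) + 1)
  list(p = p, n_mc = length(null_stats), null_stats = null_stats)
}

#' Batch GBJ statistics for many z vectors sharing one sigma
#'
#' Calibration helper: evaluates the statistic on every row of \code{Z}
#' with a single precomputed variance-correction function.
#'
#' @param Z n x d matrix of z vectors
#' @param sigma shared correlation matrix
#' @return numeric vector of n statistics
#' @export
gbjStatBatch <- function(Z, sigma) {
  stopifnot(ncol(Z) == nrow(sigma))
  .gbjBatch(Z, .pairSumFun(sigma))
}

## ---- marginal scores --------------------------------------------------

#' Covariate-adjusted marginal score statistics for a region
#'
#' Fits the null logistic model \code{phenotype ~ covariates} once, then
#' computes for every region SNP the score statistic of adding that SNP,
#' standardized to z.  \code{sigma} is the correlation of the
#' covariate-residualized dosages under the null variance weights — the
#' exact null correlation of the score statistics.  Missing dosages are
#' mean-imputed here (scores only; the genotypes are untouched).
#'
#' @param study a \linkS4class{StudyGenotypes}
#' @param region single-range \link[GenomicRanges]{GRanges}; NULL uses all
#'   variants
#' @param covariates numeric matrix (samples x q) of covariates, or NULL
#'   for intercept-only (in which case z equals the Cochran-Armitage
#'   trend-test z)
#' @param sample_idx optional subset of samples (e.g. one sex stratum)
#' @return list(z, sigma, vids, n_snps, source = "individual")
#' @export
marginalScores <- function(study, region = NULL, covariates = NULL,
                           sample_idx = NULL) {
  if (is.null(sample_idx)) sample_idx <- seq_len(ncol(study))
  si <- sampleInfo(study)[sample_idx, , drop = FALSE]
  y <- as.integer(si$phenotype == "case")
  vidx <- if (is.null(region)) seq_len(nrow(study))
          else .variantsInRegion(study, region)
  if (!length(vidx)) stop("region contains no variants")
  G <- dosage(study)[sample_idx, vidx, drop = FALSE]
  ## mean-impute missing calls
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- mu[j]
  }
  n <- length(y)
  X <- if (is.null(covariates)) matrix(1, n, 1)
       else cbind(1, as.matrix(covariates)[sample_idx, , drop = FALSE])
  fit <- glm.fit(X, y, family = binomial())
  if (!fit$converged)
    stop("null logistic model failed to converge (separation?)")
  pi_hat <- fit$fitted.values
  w <- pi_hat * (1 - pi_hat)
  U <- as.numeric(crossprod(G, y - pi_hat))
  XtWX <- crossprod(X * w, X)
  XtWG <- crossprod(X * w, G)
  B <- solve(XtWX, XtWG)                  # q x m
  GWG <- crossprod(G * sqrt(w))
  C <- GWG - crossprod(XtWG, B)           # null covariance of scores
  V <- diag(C)
  keep <- V > 1e-12
  z <- rep(NA_real_, length(V))
  z[keep] <- U[keep] / sqrt(V[keep])
  sigma <- C
  sigma[keep, keep] <- stats::cov2cor(C[keep, keep, drop = FALSE])
  sigma[!keep, ] <- 0; sigma[, !keep] <- 0
  diag(sigma) <- 1
  list(z = z, sigma = sigma, vids = variantInfo(study)$vid[vidx],
       n_snps = length(vidx), source = "individual")
}

## ---- LD pruning -------------------------------------------------------

#' Greedy windowed LD pruning
#'
#' Within each sliding window of \code{window_snps} SNPs (advancing by
#' \code{step_snps}), any retained pair with squared dosage correlation
#' above \code{r2_max} loses one member — the one with the lower minor
#' allele frequency, ties broken toward the later position — until no
#' such pair remains.  Pruning operates on raw (mean-imputed) dosage
#' correlations, before any covariate adjustment.
#'
#' @param study a \linkS4class{StudyGenotypes}
#' @param region single-range GRanges or NULL for all SNPs
#' @param r2_max squared-correlation ceiling (default 0.5, strict >
#'   removal)
#' @param window_snps,step_snps window size and step in SNPs (defaults 50
#'   and 5)
#' @return integer vector of retained variant indices (into the study's
#'   variant table), with attribute \code{"vids"}
#' @export
ldPrune <- function(study, region = NULL, r2_max = 0.5, window_snps = 50,
                    step_snps = 5) {
  vidx <- if (is.null(region)) seq_len(nrow(study))
          else .variantsInRegion(study, region)
  if (!length(vidx)) return(integer())
  G <- dosage(study)[, vidx, drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- mu[j]
  }
  m <- ncol(G)
  af <- colMeans(G) / 2
  maf <- pmin(af, 1 - af)
  keep <- rep(TRUE, m)
  starts <- if (m <= window_snps) 1L
            else unique(c(seq(1L, m - window_snps + 1L, by = step_snps),
                          m - window_snps + 1L))
  for (s in starts) {
    w <- s:min(s + window_snps - 1L, m)
    w <- w[keep[w]]
    if (length(w) < 2) next
    repeat {
      cc <- suppressWarnings(cor(G[, w, drop = FALSE]))
      cc[is.na(cc)] <- 0
      r2 <- cc^2
      diag(r2) <- 0
      mx <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
      if (r2[mx[1], mx[2]] <= r2_max) break
      a <- w[mx[1]]; b <- w[mx[2]]
      drop <- if (maf[a] < maf[b]) a
              else if (maf[b] < maf[a]) b
              else max(a, b)             # tie: later position
      keep[drop] <- FALSE
      w <- w[w != drop]
      if (length(w) < 2) break
    }
  }
  out <- vidx[keep]
  attr(out, "vids") <- variantInfo(study)$vid[out]
  out
}

## ---- region tests -----------------------------------------------------

#' GBJ region test on individual-level genotypes
#'
#' The full stage-2 contract for one region: LD-prune, compute
#' covariate-adjusted marginal scores, evaluate GBJ, attach a Monte-Carlo
#' p-value.
#'
#' @inheritParams marginalScores
#' @param r2_max,window_snps,step_snps pruning parameters ([ldPrune()])
#' @param n_mc Monte-Carlo draws for the p-value
#' @param seed integer seed
#' @return data.frame with chrom, start, end, label, n_snps_region,
#'   n_snps_tested, stat, p, method, n_mc
#' @export
testRegionIndividual <- function(study, region, covariates = NULL,
                                 sample_idx = NULL, r2_max = 0.5,
                                 window_snps = 50, step_snps = 5,
                                 n_mc = 20000, seed) {
  vidx <- .variantsInRegion(study, region)
  if (!length(vidx)) stop("region contains no variants")
  kept <- ldPrune(study, region, r2_max, window_snps, step_snps)
  sub <- .subsetStudy(study, variant_idx = kept)
  ms <- marginalScores(sub, NULL, covariates, sample_idx)
  stat <- gbjStatistic(ms)
  pv <- gbjPvalue(stat, ms$sigma, n_mc = n_mc, seed = seed)
  data.frame(chrom = as.character(GenomicRanges::seqnames(region))[1],
             start = GenomicRanges::start(region)[1],
             end = GenomicRanges::end(region)[1],
             label = .regionLabel(region),
             n_snps_region = length(vidx), n_snps_tested = length(kept),
             stat = stat, p = pv$p, method = "montecarlo", n_mc = pv$n_mc,
             stringsAsFactors = FALSE)
}

.regionLabel <- function(region) {
  lb <- S4Vectors::mcols(region)$label
  if (is.null(lb) || !length(lb))
    paste0(as.character(GenomicRanges::seqnames(region))[1], ":",
           GenomicRanges::start(region)[1], "-",
           GenomicRanges::end(region)[1])
  else lb[1]
}

#' GBJ region test from summary statistics with reference LD
#'
#' z statistics come from \code{beta/se} of the summary table; the null
#' correlation comes from a reference genotype panel.  Alleles are aligned
#' by variant id: a summary row whose a1/a2 are swapped relative to the
#' reference has its z sign flipped; rows whose alleles cannot be matched
#' are dropped and counted.
#'
#' @param sumstats data.frame in [readSummaryStats()] layout
#' @param region single-range GRanges
#' @param ld_reference a \linkS4class{StudyGenotypes} reference panel, or
#'   a correlation matrix with variant ids as dimnames
#' @param n_mc,seed Monte-Carlo p-value controls
#' @return data.frame as [testRegionIndividual()], plus
#'   \code{n_snps_dropped} (allele mismatches / not in reference)
#' @export
testRegionSummary <- function(sumstats, region, ld_reference,
                              n_mc = 20000, seed) {
  chr <- as.character(GenomicRanges::seqnames(region))[1]
  lo <- GenomicRanges::start(region)[1]
  hi <- GenomicRanges::end(region)[1]
  ss <- sumstats[sumstats$chrom == chr & sumstats$pos >= lo &
                   sumstats$pos <= hi, , drop = FALSE]
  if (!nrow(ss)) stop("no summary-stat SNPs in region")
  if (is(ld_reference, "StudyGenotypes")) {
    vi <- variantInfo(ld_reference)
    idx <- match(ss$vid, vi$vid)
    present <- !is.na(idx)
    sign_flip <- rep(NA_real_, nrow(ss))
    sign_flip[present] <- ifelse(
      ss$a1[present] == vi$a1[idx[present]] &
        ss$a2[present] == vi$a2[idx[present]], 1,
      ifelse(ss$a1[present] == vi$a2[idx[present]] &
               ss$a2[present] == vi$a1[idx[present]], -1, NA))
    ok <- present & !is.na(sign_flip)
    n_dropped <- sum(!ok)
    if (!any(ok)) stop("no region SNPs matched the LD reference")
    G <- dosage(ld_reference)[, idx[ok], drop = FALSE]
    if (anyNA(G)) {
      mu <- colMeans(G, na.rm = TRUE)
      for (j in which(colSums(is.na(G)) > 0))
        G[is.na(G[, j]), j] <- mu[j]
    }
    sigma <- suppressWarnings(cor(G))
    sigma[is.na(sigma)] <- 0
    diag(sigma) <- 1
    z <- sign_flip[ok] * ss$beta[ok] / ss$se[ok]
  } else {
    sigma <- ld_reference
    idx <- match(ss$vid, rownames(sigma))
    ok <- !is.na(idx)
    n_dropped <- sum(!ok)
    if (!any(ok)) stop("no region SNPs matched the LD reference")
    sigma <- sigma[idx[ok], idx[ok], drop = FALSE]
    z <- ss$beta[ok] / ss$se[ok]
  }
  stat <- gbjStatistic(z, sigma)
  pv <- gbjPvalue(stat, sigma, n_mc = n_mc, seed = seed)
  data.frame(chrom = chr, start = lo, end = hi,
             label = .regionLabel(region),
             n_snps_region = nrow(ss), n_snps_tested = sum(ok),
             n_snps_dropped = n_dropped,
             stat = stat, p = pv$p, method = "montecarlo", n_mc = pv$n_mc,
             stringsAsFactors = FALSE)
}
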