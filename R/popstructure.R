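## Relatedness, principal components and ancestry-outlier flagging.

## Method-of-moments IBD machinery: expected IBS-state probabilities given
## IBD state, accumulated over SNPs from allele frequencies.
.ibsExpectations <- function(p) {
  q <- 1 - p
  list(
    e0_ibd0 = sum(2 * p^2 * q^2),
    e1_ibd0 = sum(4 * p^3 * q + 4 * p * q^3),
    e2_ibd0 = sum(p^4 + q^4 + 4 * p^2 * q^2),
    e1_ibd1 = sum(2 * p^2 * q + 2 * p * q^2),
    e2_ibd1 = sum(p^3 + q^3 + p^2 * q + p * q^2))
}

#' Method-of-moments relatedness (pi-hat) for one sample pair
#'
#' Estimates the genome-wide proportion of alleles shared identical by
#' descent from observed identity-by-state counts and allele frequencies:
#' the IBD-state probabilities P(IBD = 0, 1, 2) solve the moment equations
#' relating expected and observed IBS-state counts, and
#' \code{pi_hat = P(IBD=1)/2 + P(IBD=2)}.
#'
#' @param study a \linkS4class{StudyGenotypes}
#' @param sid_a,sid_b sample ids
#' @param min_overlap minimum shared non-missing SNPs (default 100)
#' @return data.frame sid_a, sid_b, pi_hat, n_snps (pi_hat clipped to
#'   [0, 1.02]: small estimator overshoot is tolerated, larger values are
#'   capped)
#' @export
piHat <- function(study, sid_a, sid_b, min_overlap = 100) {
  G <- dosage(study)
  ia <- match(sid_a, rownames(G))
  ib <- match(sid_b, rownames(G))
  if (is.na(ia) || is.na(ib)) stop("unknown sample id")
  ga <- G[ia, ]
  gb <- G[ib, ]
  af <- colMeans(G, na.rm = TRUE) / 2
  ok <- !is.na(ga) & !is.na(gb) & af > 0 & af < 1
  if (sum(ok) < min_overlap)
    stop("insufficient overlapping non-missing SNPs: ", sum(ok))
  ga <- ga[ok]; gb <- gb[ok]; p <- af[ok]
  ibs <- 2 - abs(ga - gb)
  n0 <- sum(ibs == 0); n1 <- sum(ibs == 1); n2 <- sum(ibs == 2)
  ex <- .ibsExpectations(p)
  n <- length(p)
  z0 <- n0 / ex$e0_ibd0
  z1 <- (n1 - z0 * ex$e1_ibd0) / ex$e1_ibd1
  z2 <- (n2 - z0 * ex$e2_ibd0 - z1 * ex$e2_ibd1) / n
  z0 <- max(z0, 0); z1 <- max(z1, 0); z2 <- max(z2, 0)
  s <- z0 + z1 + z2
  if (s > 0) { z0 <- z0 / s; z1 <- z1 / s; z2 <- z2 / s }
  pi_hat <- min(z1 / 2 + z2, 1.02)
  data.frame(sid_a = sid_a, sid_b = sid_b, pi_hat = pi_hat,
             n_snps = length(p), stringsAsFactors = FALSE)
}

#' All-pairs pi-hat table
#'
#' @param study a \linkS4class{StudyGenotypes}
#' @param min_overlap as in [piHat()]
#' @return data.frame of all sample pairs with pi_hat
#' @export
piHatMatrix <- function(study, min_overlap = 100) {
  sids <- sampleInfo(study)$sid
  n <- length(sids)
  out <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + 1L
    out[[k]] <- piHat(study, sids[i], sids[j], min_overlap)
  }
  do.call(rbind, out)
}

#' Remove related samples
#'
#' Greedy exclusion: while any pair exceeds \code{threshold} (strictly),
#' drop the sample involved in the most flagged pairs (so a shared member
#' of several pairs goes first and the removal set stays minimal on small
#' families); ties are broken toward the lower genotype call rate, then
#' toward the lexicographically larger sample id.  The default cutoff
#' 0.1875 is the midpoint between the expected sharing of second-degree
#' (0.25) and third-degree (0.125) relatives.
#'
#' @param study a \linkS4class{StudyGenotypes}
#' @param threshold pi-hat above which a pair is flagged (default 0.1875)
#' @param pairs optional precomputed [piHatMatrix()] output
#' @return list(study = filtered study, removed = character sids,
#'   pairs = flagged pair table)
#' @export
relatednessFilter <- function(study, threshold = 0.1875, pairs = NULL) {
  if (is.null(pairs)) pairs <- piHatMatrix(study)
  flagged <- pairs[pairs$pi_hat > threshold, , drop = FALSE]
  G <- dosage(study)
  cr <- rowMeans(!is.na(G))
  names(cr) <- rownames(G)
  removed <- character()
  active <- flagged
  while (nrow(active)) {
    deg <- table(c(active$sid_a, active$sid_b))
    cand <- names(deg)[deg == max(deg)]
    cand <- cand[cr[cand] == min(cr[cand])]
    drop <- max(cand)
    removed <- c(removed, drop)
    active <- active[active$sid_a != drop & active$sid_b != drop, ,
                     drop = FALSE]
  }
  keep <- !(sampleInfo(study)$sid %in% removed)
  list(study = .subsetStudy(study, sample_idx = which(keep)),
       removed = removed, pairs = flagged)
}

## Randomized SVD (Halko-Martinsson-Tropp subspace iteration) for the
## top-k singular structure; deterministic via an internal fixed seed
## whose consumption is invisible to the caller's RNG stream.
.randomizedSvd <- function(X, k, oversample = 10, iters = 3) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(280731L)
  l <- min(k + oversample, min(dim(X)))
  Q <- qr.Q(qr(X %*% matrix(rnorm(ncol(X) * l), ncol = l)))
  for (i in seq_len(iters)) {
    Q <- qr.Q(qr(crossprod(X, Q)))
    Q <- qr.Q(qr(X %*% Q))
  }
  B <- crossprod(Q, X)                    # l x m
  sv <- svd(B, nu = k, nv = k)
  list(u = Q %*% sv$u, d = sv$d, v = sv$v)
}

#' Principal components of the genotype matrix
#'
#' Missing dosages are mean-imputed (for the PCA only) and each SNP is
#' centred and scaled by \code{sqrt(2 maf (1 - maf))}; the top-k right
#' singular structure of the standardized sample x SNP matrix gives the
#' scores.  Sign convention: the largest-magnitude entry of each score
#' column is positive.
#'
#' @param study a \linkS4class{StudyGenotypes}
#' @param k number of components (default 7)
#' @return list(scores = sample x k matrix, loadings = SNP x k matrix,
#'   eigenvalues = k values, non-increasing)
#' @export
computePCs <- function(study, k = 7) {
  G <- dosage(study)
  n <- nrow(G)
  af <- colMeans(G, na.rm = TRUE) / 2
  keep <- af > 0 & af < 1 & !is.na(af)
  G <- G[, keep, drop = FALSE]
  af <- af[keep]
  X <- sweep(G, 2, 2 * af)
  X[is.na(X)] <- 0           # mean imputation after centring
  X <- sweep(X, 2, sqrt(2 * af * (1 - af)), "/")
  k_eff <- min(k, n - 1, ncol(X))
  if (k_eff < k)
    warning("rank supports only ", k_eff, " components (requested ", k,
            ")")
  if (min(dim(X)) <= 600) {
    sv <- svd(X, nu = k_eff, nv = k_eff)
  } else {
    ## randomized subspace iteration for the top components: large
    ## genotype matrices only need k << min(n, m) singular vectors
    sv <- .randomizedSvd(X, k_eff)
  }
  rank_eff <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (rank_eff < k_eff) {
    warning("matrix rank supports only ", rank_eff,
            " components (requested ", k, ")")
    k_eff <- max(rank_eff, 1L)
  }
  scores <- sv$u[, seq_len(k_eff), drop = FALSE] %*%
    diag(sv$d[seq_len(k_eff)], k_eff)
  ## sign convention
  for (j in seq_len(k_eff)) {
    s <- sign(scores[which.max(abs(scores[, j])), j])
    if (s < 0) { scores[, j] <- -scores[, j]; sv$v[, j] <- -sv$v[, j] }
  }
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k_eff))
  list(scores = scores, loadings = sv$v[, seq_len(k_eff), drop = FALSE],
       eigenvalues = sv$d[seq_len(k_eff)]^2 / max(n - 1, 1))
}

#' Flag ancestry outliers on PC1/PC2
#'
#' A deterministic surrogate for visual outlier removal against a
#' reference cluster: samples whose robust z-score (median/MAD of the
#' reference subset) on PC1 or PC2 exceeds \code{n_sd} are flagged.  A
#' degenerate MAD of zero falls back to the reference SD with a warning.
#'
#' @param pcs [computePCs()] output
#' @param reference_mask logical or index vector selecting the reference
#'   samples (>= 20)
#' @param n_sd flag threshold in robust SD units (default 6)
#' @return character vector of flagged sample ids
#' @export
ancestryOutliers <- function(pcs, reference_mask, n_sd = 6) {
  S <- pcs$scores[, 1:2, drop = FALSE]
  ref <- S[reference_mask, , drop = FALSE]
  if (nrow(ref) < 20) stop("reference subset must have >= 20 samples")
  flagged <- rep(FALSE, nrow(S))
  for (j in 1:2) {
    med <- median(ref[, j])
    scale <- mad(ref[, j])
    if (scale == 0) {
      warning("MAD is zero on PC", j, "; falling back to SD")
      scale <- sd(ref[, j])
    }
    if (scale == 0) next
    flagged <- flagged | abs(S[, j] - med) / scale > n_sd
  }
  rownames(S)[flagged]
}
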