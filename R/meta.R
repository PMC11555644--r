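## Stage 4: per-SNP logistic association, sample-size-weighted Z
## fixed-effects meta-analysis, sex-difference testing and Bonferroni
## ledgers.

#' Per-SNP covariate-adjusted logistic association
#'
#' Wald estimate for one SNP's log-odds per effect-allele copy, adjusted
#' for the supplied covariates; the 95 percent CI is
#' \code{exp(beta +/- 1.96 se)}.
#'
#' @param study a \linkS4class{StudyGenotypes}
#' @param vid variant id
#' @param covariates numeric matrix (samples x q) or NULL
#' @param sample_idx optional sample subset (e.g. one sex)
#' @return data.frame vid, beta, se, or_, l95, u95, p, n_case, n_ctrl
#' @export
snpLogistic <- function(study, vid, covariates = NULL,
                        sample_idx = NULL) {
  if (is.null(sample_idx)) sample_idx <- seq_len(ncol(study))
  si <- sampleInfo(study)[sample_idx, , drop = FALSE]
  j <- match(vid, variantInfo(study)$vid)
  if (is.na(j)) stop("unknown variant id: ", vid)
  g <- dosage(study)[sample_idx, j]
  y <- as.integer(si$phenotype == "case")
  keep <- !is.na(g)
  g <- g[keep]; y2 <- y[keep]
  if (length(unique(g)) < 2)
    stop("constant genotype for ", vid, ": effect not estimable")
  X <- if (is.null(covariates)) cbind(`(Intercept)` = rep(1, sum(keep)))
       else cbind(1, as.matrix(covariates)[sample_idx, , drop = FALSE][
         keep, , drop = FALSE])
  Xg <- cbind(X, g = g)
  fit <- glm.fit(Xg, y2, family = binomial())
  if (!fit$converged) stop("logistic fit failed to converge for ", vid)
  beta <- fit$coefficients["g"]
  V <- tryCatch(solve(crossprod(Xg * sqrt(fit$weights))),
                error = function(e)
                  stop("singular information matrix (separation?) for ",
                       vid))
  se <- sqrt(V["g", "g"])
  p <- 2 * pnorm(abs(beta / se), lower.tail = FALSE)
  data.frame(vid = vid, beta = unname(beta), se = se,
             or_ = exp(unname(beta)),
             l95 = exp(unname(beta) - 1.96 * se),
             u95 = exp(unname(beta) + 1.96 * se), p = p,
             n_case = sum(y2 == 1), n_ctrl = sum(y2 == 0),
             stringsAsFactors = FALSE)
}

#' Recover (beta, se) from a printed OR and 95 percent CI
#'
#' \code{beta = ln OR}; \code{se = (ln U95 - ln L95) / (2 x 1.96)}.  Used
#' to reconstruct Wald z statistics from published association tables.
#'
#' @param or_,l95,u95 odds ratio and CI bounds, 0 < l95 < or_ < u95
#' @return list(beta, se, z, p) with the two-sided Wald p
#' @export
betaFromOrCi <- function(or_, l95, u95) {
  stopifnot(l95 > 0, l95 < or_, or_ < u95)
  beta <- log(or_)
  se <- (log(u95) - log(l95)) / (2 * 1.96)
  z <- beta / se
  list(beta = beta, se = se, z = z,
       p = 2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Effective case-control sample size
#'
#' \code{4 / (1/n_case + 1/n_ctrl)}: the size of a balanced study carrying
#' the same information; the default meta-analysis weight.
#'
#' @param n_case,n_ctrl group sizes (> 0)
#' @return effective sample size
#' @examples effectiveN(1000, 1000)  # 2000
#' @export
effectiveN <- function(n_case, n_ctrl) {
  stopifnot(all(n_case > 0), all(n_ctrl > 0))
  4 / (1 / n_case + 1 / n_ctrl)
}

#' Sample-size-weighted Z (Stouffer) meta-analysis for one SNP
#'
#' Per study, \code{z_i = sign_i * qnorm(1 - p_i / 2)}; the combined
#' statistic is \code{z_meta = sum(sqrt(w_i) z_i) / sqrt(sum(w_i))} with
#' \code{w_i} the study weight, and \code{p_meta = 2 (1 - Phi(|z_meta|))}.
#' Effective sample size ([effectiveN()]) is the default weight; total
#' sample size is available as an alternative mode.
#'
#' @param p per-study two-sided p-values in (0, 1); exact zeros are
#'   clipped to the smallest representable double with a warning
#' @param direction per-study effect signs (+1/-1, or "+"/"-")
#' @param n_case,n_ctrl per-study group sizes
#' @param weighting "effective" (default) or "total"
#' @return data.frame z_meta, p_meta, k, directions
#' @export
weightedZMeta <- function(p, direction, n_case, n_ctrl,
                          weighting = c("effective", "total")) {
  weighting <- match.arg(weighting)
  stopifnot(length(p) >= 2, length(direction) == length(p),
            length(n_case) == length(p), length(n_ctrl) == length(p))
  if (is.character(direction))
    direction <- ifelse(direction %in% c("+", "+1"), 1, -1)
  stopifnot(all(direction %in% c(-1, 1)))
  if (any(p <= 0)) {
    warning("p = 0 input clipped to the smallest representable value")
    p[p <= 0] <- .Machine$double.xmin
  }
  stopifnot(all(p <= 1))
  z <- direction * qnorm(p / 2, lower.tail = FALSE)
  w <- switch(weighting,
              effective = effectiveN(n_case, n_ctrl),
              total = n_case + n_ctrl)
  z_meta <- sum(sqrt(w) * z) / sqrt(sum(w))
  data.frame(z_meta = z_meta,
             p_meta = 2 * pnorm(abs(z_meta), lower.tail = FALSE),
             k = length(p),
             directions = paste(ifelse(direction > 0, "+", "-"),
                                collapse = ""),
             stringsAsFactors = FALSE)
}

#' Sex difference in effect size
#'
#' \code{beta_diff = beta_female - beta_male},
#' \code{se_diff = sqrt(se_female^2 + se_male^2)}, two-sided normal p.
#'
#' @param female,male single-row data.frames with \code{vid}, \code{beta},
#'   \code{se} (e.g. [snpLogistic()] rows, or reconstructed via
#'   [betaFromOrCi()])
#' @return data.frame vid, beta_diff, se_diff, z_diff, p_diff
#' @export
sexDifference <- function(female, male) {
  if (!is.null(female$vid) && !is.null(male$vid) &&
      !identical(as.character(female$vid), as.character(male$vid)))
    stop("female and male rows refer to different variants")
  beta_diff <- female$beta - male$beta
  se_diff <- sqrt(female$se^2 + male$se^2)
  z <- beta_diff / se_diff
  data.frame(vid = if (is.null(female$vid)) NA_character_
             else as.character(female$vid),
             beta_diff = beta_diff, se_diff = se_diff, z_diff = z,
             p_diff = 2 * pnorm(abs(z), lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05)
#' @param m number of tests (>= 1)
#' @return \code{alpha / m}
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Meta-analyze summary-statistic tables across studies
#'
#' Joins per-study summary tables by variant id (allele-aligning to the
#' first study: swapped a1/a2 flips the effect sign; unmatched alleles
#' drop the study for that SNP) and runs [weightedZMeta()] per SNP.
#'
#' @param tables named list of data.frames in [readSummaryStats()] layout
#' @param weighting as in [weightedZMeta()]
#' @param min_studies minimum studies present per SNP (default 2)
#' @return data.frame vid, chrom, pos, k, z_meta, p_meta, directions
#' @export
metaSummaryStats <- function(tables, weighting = "effective",
                             min_studies = 2) {
  stopifnot(length(tables) >= 2)
  ref <- tables[[1]]
  vids <- ref$vid
  out <- vector("list", length(vids))
  for (i in seq_along(vids)) {
    v <- vids[i]
    ps <- dirs <- nc <- nn <- numeric(0)
    for (tb in tables) {
      r <- tb[tb$vid == v, , drop = FALSE]
      if (nrow(r) != 1) next
      flip <- if (r$a1[1] == ref$a1[i] && r$a2[1] == ref$a2[i]) 1
              else if (r$a1[1] == ref$a2[i] && r$a2[1] == ref$a1[i]) -1
              else NA
      if (is.na(flip)) next
      b <- r$beta[1] * flip
      ps <- c(ps, max(r$p[1], .Machine$double.xmin))
      dirs <- c(dirs, if (b >= 0) 1 else -1)
      nc <- c(nc, r$n_case[1]); nn <- c(nn, r$n_ctrl[1])
    }
    if (length(ps) < min_studies) next
    mz <- weightedZMeta(ps, dirs, nc, nn, weighting = weighting)
    out[[i]] <- data.frame(vid = v, chrom = ref$chrom[i],
                           pos = ref$pos[i], mz,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(vid = character(), chrom = character(),
                      pos = numeric(), z_meta = numeric(),
                      p_meta = numeric(), k = integer(),
                      directions = character())
  rownames(res) <- NULL
  res
}

#' GBJ region test on meta-analysis z statistics
#'
#' The per-SNP meta z's for one region, with LD from a reference panel,
#' fed through the summary-statistics GBJ machinery.
#'
#' @param meta [metaSummaryStats()] output
#' @param reg single-range GRanges
#' @param ld_reference \linkS4class{StudyGenotypes} reference panel
#' @param n_mc,seed Monte-Carlo controls
#' @return data.frame as [testRegionSummary()]
#' @export
metaRegionTest <- function(meta, reg, ld_reference, n_mc = 20000, seed) {
  chr <- as.character(GenomicRanges::seqnames(reg))[1]
  lo <- GenomicRanges::start(reg)[1]
  hi <- GenomicRanges::end(reg)[1]
  mm <- meta[meta$chrom == chr & meta$pos >= lo & meta$pos <= hi, ,
             drop = FALSE]
  if (!nrow(mm)) stop("no meta-analyzed SNPs in region")
  vi <- variantInfo(ld_reference)
  idx <- match(mm$vid, vi$vid)
  ok <- !is.na(idx)
  if (!any(ok)) stop("no region SNPs matched the LD reference")
  G <- dosage(ld_reference)[, idx[ok], drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- mu[j]
  }
  sigma <- suppressWarnings(cor(G))
  sigma[is.na(sigma)] <- 0
  diag(sigma) <- 1
  z <- mm$z_meta[ok]
  stat <- gbjStatistic(z, sigma)
  pv <- gbjPvalue(stat, sigma, n_mc = n_mc, seed = seed)
  data.frame(chrom = chr, start = lo, end = hi,
             label = .regionLabel(reg),
             n_snps_region = nrow(mm), n_snps_tested = sum(ok),
             n_snps_dropped = sum(!ok),
             stat = stat, p = pv$p, method = "montecarlo",
             n_mc = pv$n_mc, stringsAsFactors = FALSE)
}
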