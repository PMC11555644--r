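## SNP- and sample-level quality control with an auditable exclusion
## cascade.  Sample filters run first, SNP filters second (call rates are
## computed on retained samples), matching the usual PLINK ordering.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the allele counts: given the minor
#' allele total, heterozygote counts of the same parity are enumerated
#' under the standard conditional distribution and the p-value is the sum
#' of probabilities no larger than that of the observed count.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom, het, hom); at least one > 0
#' @return two-sided exact p-value
#' @examples
#' hweExactPvalue(0, 2, 0)    # 1.0: both attainable tables qualify
#' hweExactPvalue(100, 0, 100) # extreme heterozygote deficit
#' @export
hweExactPvalue <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("all genotype counts are zero")
  n_minor <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  if (n_minor == 0) return(1)
  ## heterozygote counts share the parity of the minor-allele total
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  hom_min <- (n_minor - hets) / 2
  hom_maj <- n - hets - hom_min
  ## P(het | allele counts) ~ 2^het * n! / (hom_min! het! hom_maj!),
  ## normalized; work in logs
  lp <- hets * log(2) - lfactorial(hom_min) - lfactorial(hets) -
    lfactorial(hom_maj)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  obs <- which(hets == n_ab)
  if (!length(obs)) stop("observed het count has wrong parity")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Differential-missingness test between cases and controls
#'
#' Two-sided Fisher exact test on the 2x2 table of missing/observed calls
#' by phenotype; used to catch SNPs whose call rate differs systematically
#' between the groups.
#'
#' @param miss_case,n_case missing calls and total samples among cases
#' @param miss_ctrl,n_ctrl likewise among controls
#' @return two-sided p-value
#' @export
differentialMissingnessPvalue <- function(miss_case, n_case, miss_ctrl,
                                          n_ctrl) {
  stopifnot(miss_case <= n_case, miss_ctrl <= n_ctrl)
  if (n_case == 0 || n_ctrl == 0) stop("zero-size phenotype group")
  tab <- matrix(c(miss_case, n_case - miss_case,
                  miss_ctrl, n_ctrl - miss_ctrl), nrow = 2)
  fisher.test(tab)$p.value
}

.emptyQcReport <- function() {
  list(filters = data.frame(filter = character(), unit = character(),
                            removed = integer(), retained = integer(),
                            stringsAsFactors = FALSE),
       snp_stats = NULL, sample_stats = NULL)
}

.addFilter <- function(report, filter, unit, removed, retained) {
  report$filters <- rbind(report$filters,
                          data.frame(filter = filter, unit = unit,
                                     removed = as.integer(removed),
                                     retained = as.integer(retained),
                                     stringsAsFactors = FALSE))
  report
}

#' Sample-level quality filters
#'
#' Removes samples with genotype call rate below \code{call_rate_min} and
#' samples with missing phenotype or sex.  Always run before
#' [snpFilters()] so that SNP call rates are computed on retained samples.
#'
#' @param study a \linkS4class{StudyGenotypes}
#' @param call_rate_min minimum per-sample call rate (default 0.95)
#' @return list(study = filtered study, report = QC report)
#' @export
sampleFilters <- function(study, call_rate_min = 0.95) {
  stopifnot(is(study, "StudyGenotypes"), nrow(study) > 0, ncol(study) > 0)
  report <- .emptyQcReport()
  si <- sampleInfo(study)
  G <- dosage(study)
  cr <- rowMeans(!is.na(G))
  keep_cr <- cr >= call_rate_min
  report <- .addFilter(report, "sample_call_rate", "sample",
                       sum(!keep_cr), sum(keep_cr))
  keep_meta <- !is.na(si$phenotype) & !is.na(si$sex)
  keep <- keep_cr & keep_meta
  report <- .addFilter(report, "sample_missing_metadata", "sample",
                       sum(keep_cr & !keep_meta), sum(keep))
  report$sample_stats <- data.frame(sid = si$sid, call_rate = cr,
                                    retained = keep)
  if (!any(keep)) stop("all samples removed by sample filters")
  list(study = .subsetStudy(study, sample_idx = which(keep)),
       report = report)
}

#' SNP-level quality filters
#'
#' Removes SNPs that fail any of, in order: call rate below
#' \code{call_rate_min}; differential missingness between cases and
#' controls at \code{diffmiss_alpha}; minor allele frequency strictly below
#' \code{maf_min}; exact Hardy-Weinberg p below \code{hwe_alpha} in
#' controls — evaluated in all controls and additionally within male-only
#' and female-only controls to catch sex-specific genotyping error.  The
#' report itemizes removals per rule in application order (a SNP is charged
#' to the first rule it fails).
#'
#' @param study a \linkS4class{StudyGenotypes}
#' @param call_rate_min minimum SNP call rate (default 0.95)
#' @param maf_min minimum minor allele frequency, strict (default 0.01)
#' @param hwe_alpha HWE exact-test threshold, strict (default 1e-5)
#' @param diffmiss_alpha differential-missingness threshold (default 1e-5)
#' @return list(study = filtered study, report = QC report with per-SNP
#'   statistics)
#' @export
snpFilters <- function(study, call_rate_min = 0.95, maf_min = 0.01,
                       hwe_alpha = 1e-5, diffmiss_alpha = 1e-5) {
  stopifnot(is(study, "StudyGenotypes"), nrow(study) > 0, ncol(study) > 0)
  report <- .emptyQcReport()
  G <- dosage(study)                      # samples x variants
  si <- sampleInfo(study)
  vi <- variantInfo(study)
  is_case <- si$phenotype == "case"
  is_ctrl <- !is_case
  m <- ncol(G)
  call_rate <- colMeans(!is.na(G))
  miss_case <- colSums(is.na(G[is_case, , drop = FALSE]))
  miss_ctrl <- colSums(is.na(G[is_ctrl, , drop = FALSE]))
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hweP <- function(rows) {
    vapply(seq_len(m), function(j) {
      g <- G[rows, j]
      g <- g[!is.na(g)]
      if (!length(g)) return(NA_real_)
      hweExactPvalue(sum(g == 0), sum(g == 1), sum(g == 2))
    }, numeric(1))
  }
  hwe_all <- hweP(which(is_ctrl))
  hwe_m <- hweP(which(is_ctrl & si$sex == "male"))
  hwe_f <- hweP(which(is_ctrl & si$sex == "female"))
  dm <- vapply(seq_len(m), function(j)
    differentialMissingnessPvalue(miss_case[j], sum(is_case),
                                  miss_ctrl[j], sum(is_ctrl)),
    numeric(1))
  fail_cr <- call_rate < call_rate_min
  fail_dm <- !fail_cr & dm < diffmiss_alpha
  fail_maf <- !fail_cr & !fail_dm & maf < maf_min
  fail_hwe <- !fail_cr & !fail_dm & !fail_maf &
    ((!is.na(hwe_all) & hwe_all < hwe_alpha) |
       (!is.na(hwe_m) & hwe_m < hwe_alpha) |
       (!is.na(hwe_f) & hwe_f < hwe_alpha))
  keep <- !(fail_cr | fail_dm | fail_maf | fail_hwe)
  left <- m
  for (nm in c("snp_call_rate", "snp_differential_missingness", "snp_maf",
               "snp_hwe_controls")) {
    fl <- switch(nm, snp_call_rate = fail_cr,
                 snp_differential_missingness = fail_dm,
                 snp_maf = fail_maf, snp_hwe_controls = fail_hwe)
    left <- left - sum(fl)
    report <- .addFilter(report, nm, "snp", sum(fl), left)
  }
  report$snp_stats <- data.frame(
    vid = vi$vid, call_rate = call_rate, maf = maf,
    hwe_p_controls = hwe_all, hwe_p_male_controls = hwe_m,
    hwe_p_female_controls = hwe_f, diffmiss_p = dm,
    ambiguous = isStrandAmbiguous(vi$a1, vi$a2), retained = keep)
  list(study = .subsetStudy(study, variant_idx = which(keep)),
       report = report)
}

#' Duplicate-sample detection by genotype concordance
#'
#' Flags sample pairs whose exact genotype concordance over shared
#' non-missing SNPs exceeds \code{concordance_min}; used for duplicate
#' detection within and across studies.
#'
#' @param study_a,study_b StudyGenotypes (may be the same object for
#'   within-study duplicate scan)
#' @param concordance_min minimum concordance to flag (default 0.95)
#' @param min_overlap minimum shared non-missing SNPs per pair (default 50)
#' @return data.frame sid_a, sid_b, concordance, n_overlap
#' @export
duplicateScan <- function(study_a, study_b = study_a,
                          concordance_min = 0.95, min_overlap = 50) {
  va <- variantInfo(study_a)$vid
  vb <- variantInfo(study_b)$vid
  shared <- intersect(va, vb)
  Ga <- dosage(study_a)[, match(shared, va), drop = FALSE]
  Gb <- dosage(study_b)[, match(shared, vb), drop = FALSE]
  same_obj <- identical(study_a, study_b)
  out <- list()
  for (i in seq_len(nrow(Ga))) {
    jj <- if (same_obj) seq_len(nrow(Gb)) > i else rep(TRUE, nrow(Gb))
    if (!any(jj)) next
    cmp <- sweep(Gb[jj, , drop = FALSE], 2, Ga[i, ], "==")
    n_ov <- rowSums(!is.na(cmp))
    conc <- rowSums(cmp, na.rm = TRUE) / pmax(n_ov, 1)
    hit <- which(n_ov >= min_overlap & conc > concordance_min)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        sid_a = rownames(Ga)[i],
        sid_b = rownames(Gb)[jj][hit],
        concordance = conc[hit], n_overlap = n_ov[hit])
  }
  if (!length(out))
    return(data.frame(sid_a = character(), sid_b = character(),
                      concordance = numeric(), n_overlap = integer()))
  do.call(rbind, out)
}

#' Full QC cascade for one study
#'
#' [sampleFilters()] then [snpFilters()]; the combined report stacks the
#' two exclusion tables so the cascade can be reconstructed exactly.
#'
#' @inheritParams snpFilters
#' @param sample_call_rate_min per-sample call-rate floor (default 0.95)
#' @return list(study, report)
#' @export
qcStudy <- function(study, sample_call_rate_min = 0.95,
                    call_rate_min = 0.95, maf_min = 0.01,
                    hwe_alpha = 1e-5, diffmiss_alpha = 1e-5) {
  s1 <- sampleFilters(study, sample_call_rate_min)
  s2 <- snpFilters(s1$study, call_rate_min, maf_min, hwe_alpha,
                   diffmiss_alpha)
  report <- .emptyQcReport()
  report$filters <- rbind(s1$report$filters, s2$report$filters)
  report$sample_stats <- s1$report$sample_stats
  report$snp_stats <- s2$report$snp_stats
  list(study = s2$study, report = report)
}
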