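## Stage 1-4 orchestration: screen -> region tests -> validation ->
## meta-analysis, with the concordance selection rules, known-region
## routing, and machine-parseable decision trails.

#' Pipeline configuration
#'
#' @param strata sex strata to analyze (subset of "combined", "male",
#'   "female")
#' @param plo_min window PLO threshold for stage-1 selection (default 2:
#'   posterior odds 100 under prior odds 1)
#' @param min_studies concordance requirement (default 2)
#' @param n_boot permutation iterations for the stage-1 null gate
#'   (default 1000)
#' @param gbj_alpha per-study GBJ significance level in stages 2-3
#'   (default 0.05)
#' @param fw_alpha family-wise alpha for Bonferroni ledgers (default 0.05)
#' @param window_bp,step_bp window grid (defaults 100000 / 50000)
#' @param n_pcs principal components used as covariates (default 7)
#' @param adjust_age,adjust_sex include age / sex covariates (sex only in
#'   combined strata)
#' @param r2_max,window_snps,step_snps LD pruning (defaults 0.5, 50, 5)
#' @param n_mc Monte-Carlo draws per GBJ p-value (default 20000)
#' @param seed master seed; every stochastic stage derives its own from it
#' @param tree_prior [treePrior()] hyperparameters
#' @return a \code{pipeline_config} list
#' @export
pipelineConfig <- function(strata = c("combined", "male", "female"),
                           plo_min = 2, min_studies = 2, n_boot = 1000,
                           gbj_alpha = 0.05, fw_alpha = 0.05,
                           window_bp = 100000, step_bp = 50000,
                           n_pcs = 7, adjust_age = TRUE,
                           adjust_sex = TRUE, r2_max = 0.5,
                           window_snps = 50, step_snps = 5,
                           n_mc = 20000, seed,
                           tree_prior = treePrior()) {
  stopifnot(plo_min > 0, min_studies >= 1, gbj_alpha > 0, gbj_alpha < 1,
            step_bp > 0, step_bp <= window_bp, n_pcs >= 0)
  if (missing(seed)) stop("seed is mandatory")
  structure(list(strata = match.arg(strata, several.ok = TRUE),
                 plo_min = plo_min, min_studies = min_studies,
                 n_boot = n_boot, gbj_alpha = gbj_alpha,
                 fw_alpha = fw_alpha, window_bp = window_bp,
                 step_bp = step_bp, n_pcs = n_pcs,
                 adjust_age = adjust_age, adjust_sex = adjust_sex,
                 r2_max = r2_max, window_snps = window_snps,
                 step_snps = step_snps, n_mc = n_mc, seed = seed,
                 tree_prior = tree_prior),
            class = "pipeline_config")
}

#' Covariate design for association stages
#'
#' Age, a male indicator (combined strata only) and the first
#' \code{n_pcs} principal components, as a samples x q matrix.
#'
#' @param study a \linkS4class{StudyGenotypes}
#' @param config [pipelineConfig()]
#' @param stratum "combined", "male" or "female"
#' @return numeric covariate matrix (possibly zero columns)
#' @export
buildCovariates <- function(study, config, stratum = "combined") {
  si <- sampleInfo(study)
  cols <- list()
  if (config$adjust_sex && stratum == "combined")
    cols$male <- as.numeric(si$sex == "male")
  if (config$adjust_age && !all(is.na(si$age))) {
    age <- si$age
    age[is.na(age)] <- mean(age, na.rm = TRUE)
    cols$age <- age
  }
  if (config$n_pcs > 0) {
    pcs <- computePCs(study, k = config$n_pcs)$scores
    for (j in seq_len(ncol(pcs))) cols[[colnames(pcs)[j]]] <- pcs[, j]
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

.stratumIdx <- function(study, stratum) {
  si <- sampleInfo(study)
  if (stratum == "combined") seq_len(nrow(si))
  else which(si$sex == stratum)
}

#' Stage 1: window screen and concordance selection
#'
#' Screens every study (per stratum) on a shared window grid, selects
#' windows with PLO >= \code{plo_min} in at least \code{min_studies}
#' studies of the same stratum, bootstraps the selected windows in their
#' qualifying studies, keeps windows whose PLO beats the permutation-null
#' 95th percentile in each qualifying study, and merges contiguous
#' qualifying windows.  Candidates overlapping \code{known_regions} are
#' routed to a separate known-region list, not to the candidate list.
#'
#' @param studies named list of post-QC \linkS4class{StudyGenotypes} on a
#'   common variant map
#' @param config [pipelineConfig()]
#' @param known_regions optional GRanges of known susceptibility regions
#' @return list per stratum: candidates (GRanges with qualifying-study
#'   info), known_hits, plo_tables
#' @export
runStage1 <- function(studies, config, known_regions = NULL) {
  stopifnot(length(studies) >= config$min_studies)
  if (is.null(names(studies)))
    names(studies) <- paste0("study", seq_along(studies))
  vi <- variantInfo(studies[[1]])
  for (s in studies[-1])
    if (!identical(variantInfo(s)$vid, vi$vid))
      stop("studies must share one variant map for a common window grid")
  windows <- makeWindows(vi, config$window_bp, config$step_bp)
  out <- list()
  for (stratum in config$strata) {
    tables <- vector("list", length(studies))
    names(tables) <- names(studies)
    for (i in seq_along(studies)) {
      tables[[i]] <- screenStudy(studies[[i]], windows,
                                 prior = config$tree_prior, n_boot = 0,
                                 sex_stratum = stratum)
    }
    ## step A: concordance without the bootstrap gate
    pre <- concordanceSelect(tables, config$plo_min, config$min_studies,
                             check_boot = FALSE)
    ## bootstrap only qualifying windows in qualifying studies
    if (length(pre) && config$n_boot > 0) {
      wsel <- GenomicRanges::GRanges(
        tables[[1]]$chrom,
        IRanges::IRanges(tables[[1]]$start, tables[[1]]$end))
      hitw <- which(GenomicRanges::countOverlaps(wsel, pre) > 0)
      mcw <- S4Vectors::mcols(windows)
      for (i in seq_along(studies)) {
        idx <- .stratumIdx(studies[[i]], stratum)
        y <- as.integer(
          sampleInfo(studies[[i]])$phenotype[idx] == "case")
        G <- dosage(studies[[i]])[idx, , drop = FALSE]
        for (w in hitw) {
          if (is.na(tables[[i]]$plo[w]) ||
              tables[[i]]$plo[w] < config$plo_min) next
          g <- G[, mcw$snp_first[w]:mcw$snp_last[w], drop = FALSE]
          tables[[i]]$boot_p95[w] <- bootstrapNullPLO(
            y, g, config$tree_prior, config$n_boot,
            seed = config$seed + 1000L * i + w)$boot_p95
          tables[[i]]$boot_n[w] <- config$n_boot
        }
      }
      cand <- concordanceSelect(tables, config$plo_min,
                                config$min_studies, check_boot = TRUE)
    } else cand <- pre
    ## per-candidate qualifying studies
    if (length(cand)) {
      qual <- character(length(cand))
      for (r in seq_along(cand)) {
        qs <- character()
        for (i in seq_along(studies)) {
          tb <- tables[[i]]
          wgr <- GenomicRanges::GRanges(tb$chrom,
                   IRanges::IRanges(tb$start, tb$end))
          inr <- GenomicRanges::countOverlaps(wgr, cand[r]) > 0
          if (any(!is.na(tb$plo[inr]) &
                  tb$plo[inr] >= config$plo_min))
            qs <- c(qs, names(studies)[i])
        }
        qual[r] <- paste(qs, collapse = ",")
      }
      S4Vectors::mcols(cand)$qualifying_studies <- qual
    }
    ## route known-region overlaps out of the candidate list
    known_hits <- GenomicRanges::GRanges()
    if (!is.null(known_regions) && length(cand)) {
      ov <- GenomicRanges::countOverlaps(cand, known_regions) > 0
      known_hits <- cand[ov]
      cand <- cand[!ov]
    }
    out[[stratum]] <- list(candidates = cand, known_hits = known_hits,
                           plo_tables = tables)
  }
  structure(out, windows = windows, class = "stage1_result")
}

#' Stage 2: GBJ confirmation of stage-1 candidates
#'
#' Each candidate region is GBJ-tested in every study (covariate
#' adjusted, LD pruned).  A region is retained when at least
#' \code{min_studies} of its stage-1 qualifying studies report GBJ
#' p < \code{gbj_alpha} in the discovery stratum.  Regions that instead
#' meet the rule in a different stratum are recorded with the flag
#' \code{other_stratum} rather than dropped silently.
#'
#' @param studies as in [runStage1()]
#' @param stage1 [runStage1()] output
#' @param config [pipelineConfig()]
#' @return data.frame: one row per candidate x stratum with per-study
#'   p-values, retention decision and trail
#' @export
runStage2 <- function(studies, stage1, config) {
  if (is.null(names(studies)))
    names(studies) <- paste0("study", seq_along(studies))
  covs <- list()
  for (i in seq_along(studies)) covs[[i]] <- list()
  rows <- list()
  for (stratum in names(stage1)) {
    cand <- stage1[[stratum]]$candidates
    if (!length(cand)) next
    for (r in seq_along(cand)) {
      reg <- cand[r]
      qs <- strsplit(S4Vectors::mcols(reg)$qualifying_studies, ",")[[1]]
      pvals <- setNames(rep(NA_real_, length(studies)), names(studies))
      for (i in seq_along(studies)) {
        st <- studies[[i]]
        if (is.null(covs[[i]][[stratum]]))
          covs[[i]][[stratum]] <- buildCovariates(st, config, stratum)
        idx <- .stratumIdx(st, stratum)
        res <- tryCatch(testRegionIndividual(
          st, reg, covariates = covs[[i]][[stratum]], sample_idx = idx,
          r2_max = config$r2_max, window_snps = config$window_snps,
          step_snps = config$step_snps, n_mc = config$n_mc,
          seed = config$seed + 7000L + 100L * i + r),
          error = function(e) NULL)
        if (!is.null(res)) pvals[i] <- res$p
      }
      n_sig_qual <- sum(pvals[qs] < config$gbj_alpha, na.rm = TRUE)
      retained <- n_sig_qual >= config$min_studies
      ## other-stratum check: same region, same qualifying studies,
      ## different sex stratum
      other <- NA_character_
      if (!retained) {
        for (os in setdiff(config$strata, stratum)) {
          po <- setNames(rep(NA_real_, length(qs)), qs)
          for (nm in qs) {
            i <- match(nm, names(studies))
            st <- studies[[i]]
            if (is.null(covs[[i]][[os]]))
              covs[[i]][[os]] <- buildCovariates(st, config, os)
            idx <- .stratumIdx(st, os)
            res <- tryCatch(testRegionIndividual(
              st, reg, covariates = covs[[i]][[os]], sample_idx = idx,
              r2_max = config$r2_max, window_snps = config$window_snps,
              step_snps = config$step_snps, n_mc = config$n_mc,
              seed = config$seed + 8000L + 100L * i + r),
              error = function(e) NULL)
            if (!is.null(res)) po[nm] <- res$p
          }
          if (sum(po < config$gbj_alpha, na.rm = TRUE) >=
              config$min_studies) { other <- os; break }
        }
      }
      trail <- paste0("stage1:qualifying=", paste(qs, collapse = "+"),
                      ";stage2:p_sig_qualifying=", n_sig_qual,
                      ";decision=",
                      if (retained) "retained"
                      else if (!is.na(other))
                        paste0("other_stratum:", other)
                      else "dropped")
      row <- data.frame(label = .regionLabel(reg),
                        chrom = as.character(
                          GenomicRanges::seqnames(reg)),
                        start = GenomicRanges::start(reg),
                        end = GenomicRanges::end(reg),
                        stratum = stratum,
                        qualifying_studies = paste(qs, collapse = ","),
                        retained = retained | !is.na(other),
                        other_stratum = other, trail = trail,
                        stringsAsFactors = FALSE)
      for (nm in names(studies)) row[[paste0("gbj_p_", nm)]] <- pvals[nm]
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows))
    return(data.frame(label = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stratum = character(),
                      qualifying_studies = character(),
                      retained = logical(), other_stratum = character(),
                      trail = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stage 3: validation against a summary-statistics study
#'
#' GBJ with reference LD per retained candidate, in the candidate's own
#' stratum when a stratified table is available, plus opposite-sex checks
#' for sex-specific candidates.
#'
#' @param candidates [runStage2()] output (rows with
#'   \code{retained = TRUE} are tested)
#' @param validation either one summary-stats data.frame or a named list
#'   by stratum ("combined", "male", "female")
#' @param ld_reference \linkS4class{StudyGenotypes} reference panel
#' @param config [pipelineConfig()]
#' @return candidates with added columns validation_p,
#'   validation_stratum, validation_p_opposite, and extended trail
#' @export
runStage3 <- function(candidates, validation, ld_reference, config) {
  if (!nrow(candidates)) {
    candidates$validation_p <- numeric()
    candidates$validation_stratum <- character()
    candidates$validation_p_opposite <- numeric()
    return(candidates)
  }
  vtab <- function(stratum) {
    if (is.data.frame(validation)) return(validation)
    validation[[stratum]]
  }
  candidates$validation_p <- NA_real_
  candidates$validation_stratum <- NA_character_
  candidates$validation_p_opposite <- NA_real_
  for (r in which(candidates$retained)) {
    stratum <- candidates$stratum[r]
    reg <- region(candidates$chrom[r], candidates$start[r],
                  candidates$end[r], candidates$label[r])
    tb <- vtab(stratum)
    used <- stratum
    if (is.null(tb)) { tb <- vtab("combined"); used <- "combined" }
    res <- tryCatch(testRegionSummary(tb, reg, ld_reference,
                                      n_mc = config$n_mc,
                                      seed = config$seed + 9000L + r),
                    error = function(e) NULL)
    if (is.null(res)) {
      candidates$trail[r] <- paste0(candidates$trail[r],
                                    ";stage3:coverage_warning")
      next
    }
    candidates$validation_p[r] <- res$p
    candidates$validation_stratum[r] <- used
    if (stratum %in% c("male", "female")) {
      opp <- if (stratum == "male") "female" else "male"
      tbo <- vtab(opp)
      if (!is.null(tbo)) {
        reso <- tryCatch(testRegionSummary(tbo, reg, ld_reference,
                                           n_mc = config$n_mc,
                                           seed = config$seed + 9500L +
                                             r),
                         error = function(e) NULL)
        if (!is.null(reso))
          candidates$validation_p_opposite[r] <- reso$p
      }
    }
    candidates$trail[r] <- paste0(candidates$trail[r], ";stage3:p=",
                                  signif(candidates$validation_p[r], 3),
                                  ",stratum=", used)
  }
  candidates
}

#' Stage 4: SNP meta-analysis, sex-difference tests and Bonferroni ledger
#'
#' For each retained candidate: per-SNP covariate-adjusted logistic
#' regression in every genotype study (candidate stratum), a weighted-Z
#' meta-analysis including the summary-only validation study, the
#' region's lowest meta p SNP, and — for sex-specific candidates — the
#' per-study and pooled sex-difference test at that SNP.  The Bonferroni
#' thresholds \code{fw_alpha / n_regions} and \code{fw_alpha / n_snps}
#' are applied and reported.
#'
#' @param studies genotype studies (as stage 1)
#' @param validation summary table(s) as in [runStage3()]
#' @param candidates [runStage3()] output
#' @param config [pipelineConfig()]
#' @param ld_reference optional reference panel; when supplied, a GBJ
#'   region test on the meta z's is added per candidate
#' @return list(report = per-candidate data.frame, snp_meta = per-SNP
#'   meta table, thresholds = ledger)
#' @export
runStage4 <- function(studies, validation, candidates, config,
                      ld_reference = NULL) {
  if (length(studies) + (!is.null(validation)) < 2)
    stop("meta-analysis requires at least two studies")
  if (is.null(names(studies)))
    names(studies) <- paste0("study", seq_along(studies))
  act <- which(candidates$retained)
  snp_meta_all <- list()
  report <- candidates
  report$meta_p_lowest <- NA_real_
  report$meta_lowest_vid <- NA_character_
  report$meta_lowest_z <- NA_real_
  report$sexdiff_p <- NA_real_
  report$meta_region_p <- NA_real_
  covs <- lapply(studies, function(s) list())
  vtab <- function(stratum) {
    if (is.data.frame(validation)) return(validation)
    if (is.null(validation)) return(NULL)
    validation[[stratum]]
  }
  sumstatsFor <- function(stratum, reg) {
    ## per-study summary tables for the region's SNPs in this stratum
    tabs <- list()
    for (i in seq_along(studies)) {
      st <- studies[[i]]
      vidx <- .variantsInRegion(st, reg)
      if (!length(vidx)) next
      if (is.null(covs[[i]][[stratum]]))
        covs[[i]][[stratum]] <<- buildCovariates(st, config, stratum)
      idx <- .stratumIdx(st, stratum)
      vi <- variantInfo(st)[vidx, , drop = FALSE]
      rows <- lapply(vi$vid, function(v)
        tryCatch(snpLogistic(st, v, covs[[i]][[stratum]], idx),
                 error = function(e) NULL))
      okr <- !vapply(rows, is.null, logical(1))
      if (!any(okr)) next
      tb <- do.call(rbind, rows[okr])
      tb <- cbind(vi[okr, c("chrom", "pos", "vid", "a1", "a2")],
                  tb[, c("beta", "se", "p", "n_case", "n_ctrl")])
      tabs[[names(studies)[i]]] <- tb
    }
    vt <- vtab(stratum)
    if (!is.null(vt)) {
      chr <- as.character(GenomicRanges::seqnames(reg))[1]
      sel <- vt$chrom == chr &
        vt$pos >= GenomicRanges::start(reg)[1] &
        vt$pos <= GenomicRanges::end(reg)[1]
      if (any(sel)) tabs$validation <- vt[sel, , drop = FALSE]
    }
    tabs
  }
  for (r in act) {
    stratum <- candidates$stratum[r]
    reg <- region(candidates$chrom[r], candidates$start[r],
                  candidates$end[r], candidates$label[r])
    tabs <- sumstatsFor(stratum, reg)
    if (length(tabs) < 2) {
      report$trail[r] <- paste0(report$trail[r],
                                ";stage4:insufficient_studies")
      next
    }
    meta <- metaSummaryStats(tabs)
    if (!nrow(meta)) next
    meta$region <- candidates$label[r]
    meta$stratum <- stratum
    snp_meta_all[[length(snp_meta_all) + 1L]] <- meta
    best <- which.min(meta$p_meta)
    report$meta_p_lowest[r] <- meta$p_meta[best]
    report$meta_lowest_vid[r] <- meta$vid[best]
    report$meta_lowest_z[r] <- meta$z_meta[best]
    ## sex-difference at the lowest-p SNP for sex-specific candidates:
    ## pool the per-sex estimates across studies by inverse variance,
    ## then contrast female - male
    if (stratum %in% c("male", "female")) {
      v <- meta$vid[best]
      perSex <- function(sx) {
        bs <- ses <- numeric(0)
        for (i in seq_along(studies)) {
          st <- studies[[i]]
          if (is.null(covs[[i]][[sx]]))
            covs[[i]][[sx]] <- buildCovariates(st, config, sx)
          idx <- .stratumIdx(st, sx)
          row <- tryCatch(snpLogistic(st, v, covs[[i]][[sx]], idx),
                          error = function(e) NULL)
          if (!is.null(row)) { bs <- c(bs, row$beta)
                               ses <- c(ses, row$se) }
        }
        vt <- vtab(sx)
        if (!is.null(vt)) {
          rr <- vt[vt$vid == v, , drop = FALSE]
          if (nrow(rr) == 1) { bs <- c(bs, rr$beta)
                               ses <- c(ses, rr$se) }
        }
        if (!length(bs)) return(NULL)
        w <- 1 / ses^2
        list(beta = sum(w * bs) / sum(w), se = sqrt(1 / sum(w)))
      }
      f <- perSex("female"); m <- perSex("male")
      if (!is.null(f) && !is.null(m)) {
        sd_row <- sexDifference(
          data.frame(vid = v, beta = f$beta, se = f$se),
          data.frame(vid = v, beta = m$beta, se = m$se))
        report$sexdiff_p[r] <- sd_row$p_diff
      }
    }
    if (!is.null(ld_reference)) {
      mres <- tryCatch(metaRegionTest(meta, reg, ld_reference,
                                      n_mc = config$n_mc,
                                      seed = config$seed + 11000L + r),
                       error = function(e) NULL)
      if (!is.null(mres)) report$meta_region_p[r] <- mres$p
    }
    report$trail[r] <- paste0(report$trail[r], ";stage4:lowest=",
                              report$meta_lowest_vid[r], ",p=",
                              signif(report$meta_p_lowest[r], 3))
  }
  snp_meta <- if (length(snp_meta_all)) do.call(rbind, snp_meta_all)
              else data.frame()
  n_regions <- sum(candidates$retained)
  n_snps <- if (nrow(snp_meta)) length(unique(snp_meta$vid)) else 0L
  thresholds <- data.frame(
    ledger = c("per_region", "per_snp"),
    m = c(max(n_regions, 1L), max(n_snps, 1L)),
    threshold = c(bonferroniThreshold(config$fw_alpha,
                                      max(n_regions, 1L)),
                  bonferroniThreshold(config$fw_alpha,
                                      max(n_snps, 1L))))
  if (nrow(snp_meta))
    report$meta_significant <- !is.na(report$meta_p_lowest) &
      report$meta_p_lowest < thresholds$threshold[2]
  list(report = report, snp_meta = snp_meta, thresholds = thresholds)
}

#' PLO and GBJ scan of known susceptibility regions
#'
#' Treats each supplied region as a single analysis window: PLO and a GBJ
#' p-value per region x study x stratum.
#'
#' @param studies genotype studies
#' @param regions GRanges of known regions
#' @param config [pipelineConfig()]
#' @param gbj whether to add GBJ p-values (default TRUE)
#' @return data.frame with |regions| x |studies| x |strata| rows
#' @export
knownRegionScan <- function(studies, regions, config, gbj = TRUE) {
  if (is.null(names(studies)))
    names(studies) <- paste0("study", seq_along(studies))
  rows <- list()
  covs <- lapply(studies, function(s) list())
  if (!length(regions))
    return(data.frame(label = character(), study = character(),
                      stratum = character(), n_snps = integer(),
                      plo = numeric(), gbj_p = numeric()))
  for (r in seq_along(regions)) {
    reg <- regions[r]
    for (i in seq_along(studies)) {
      st <- studies[[i]]
      vidx <- .variantsInRegion(st, reg)
      for (stratum in config$strata) {
        idx <- .stratumIdx(st, stratum)
        plo <- NA_real_
        gp <- NA_real_
        if (length(vidx)) {
          y <- as.integer(sampleInfo(st)$phenotype[idx] == "case")
          g <- dosage(st)[idx, vidx, drop = FALSE]
          plo <- windowPLO(y, g, config$tree_prior)$plo
          if (gbj) {
            if (is.null(covs[[i]][[stratum]]))
              covs[[i]][[stratum]] <- buildCovariates(st, config,
                                                      stratum)
            res <- tryCatch(testRegionIndividual(
              st, reg, covs[[i]][[stratum]], idx,
              r2_max = config$r2_max,
              window_snps = config$window_snps,
              step_snps = config$step_snps, n_mc = config$n_mc,
              seed = config$seed + 13000L + 17L * r + i),
              error = function(e) NULL)
            if (!is.null(res)) gp <- res$p
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          label = .regionLabel(reg), study = names(studies)[i],
          stratum = stratum, n_snps = length(vidx), plo = plo,
          gbj_p = gp, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
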