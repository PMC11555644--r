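## Stage 1: sliding-window Bayesian decision-tree screen.
##
## Each window's dosage submatrix is scored by a Bayesian classification
## tree: leaves carry Beta(1,1)-Binomial marginals of the case count, the
## tree is grown greedily on splits of the form "dosage <= c" (c in {0,1},
## missing mean-imputed), and a split is kept only if it raises the tree's
## marginal likelihood including a per-split structural prior penalty of
## -ln 2.  The screen statistic is the posterior log-odds in favor of
## association, PLO = log10 of the Bayes factor of the fitted tree against
## the intercept-only (no-association) model, under prior odds 1 -- so
## PLO = 2 means the window is 100 times more likely to contain an
## associated SNP than not.

#' Default tree prior for the window screen
#'
#' @param max_depth maximum split depth (default 3)
#' @param min_leaf minimum samples per leaf (default 25)
#' @param log_split_prior structural log-prior penalty per split
#'   (default -ln 2)
#' @return list of tree hyperparameters
#' @export
treePrior <- function(max_depth = 3, min_leaf = 25,
                      log_split_prior = -log(2)) {
  list(max_depth = max_depth, min_leaf = min_leaf,
       log_split_prior = log_split_prior)
}

## Beta(1,1)-Binomial log marginal of a leaf with n1 cases, n0 controls
.leafLogMarginal <- function(n1, n0) lbeta(n1 + 1, n0 + 1)

## Greedy tree growth (compiled).  M0/M1: n x d 0/1 integer matrices of
## the split indicators g <= 0 and g <= 1 (on mean-imputed dosage).
## Returns total tree log marginal including split penalties.
.growTree <- function(y, M0, M1, prior) {
  cpp_grow_tree(as.integer(y), M0, M1, prior$max_depth, prior$min_leaf,
                prior$log_split_prior)
}

## build the split-indicator matrices for a window dosage submatrix
.splitMasks <- function(g) {
  gi <- g
  if (anyNA(gi)) {
    mu <- colMeans(gi, na.rm = TRUE)
    for (j in which(colSums(is.na(gi)) > 0))
      gi[is.na(gi[, j]), j] <- mu[j]
  }
  M0 <- gi <= 0; storage.mode(M0) <- "integer"
  M1 <- gi <= 1; storage.mode(M1) <- "integer"
  list(M0 = M0, M1 = M1)
}

#' Log marginal likelihood of a window under the Bayesian tree model
#'
#' @param y 0/1 phenotype vector (1 = case); both classes must be present
#' @param g window dosage submatrix, samples x SNPs; missing entries are
#'   mean-imputed for splitting
#' @param prior [treePrior()] hyperparameters
#' @return log marginal likelihood (nats); with no accepted split this is
#'   the Beta-Binomial log marginal of the case/control totals
#' @export
windowLogMarginal <- function(y, g, prior = treePrior()) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (is.null(dim(g))) g <- matrix(g, ncol = 1)
  stopifnot(nrow(g) == length(y), ncol(g) >= 1)
  masks <- .splitMasks(g)
  .growTree(y, masks$M0, masks$M1, prior)
}

#' Window PLO score
#'
#' \code{plo = (windowLogMarginal(y, g) - null log marginal) / ln 10},
#' i.e. the base-10 log Bayes factor of the tree model against the
#' intercept-only model; with prior odds 1 this is the posterior log-odds
#' in favor of the window containing at least one associated SNP.
#'
#' @inheritParams windowLogMarginal
#' @return list(plo, n_snps, log_marginal, null_log_marginal)
#' @export
windowPLO <- function(y, g, prior = treePrior()) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (is.null(dim(g))) g <- matrix(g, ncol = 1)
  masks <- .splitMasks(g)
  lm_tree <- .growTree(y, masks$M0, masks$M1, prior)
  lm_null <- .leafLogMarginal(sum(y), length(y) - sum(y))
  list(plo = (lm_tree - lm_null) / log(10), n_snps = ncol(g),
       log_marginal = lm_tree, null_log_marginal = lm_null)
}

#' Permutation null for the window PLO
#'
#' Phenotype labels are permuted (the case:control ratio is preserved
#' exactly) and the PLO recomputed \code{n_boot} times; the 95th
#' percentile (type-7 quantile) of the null draws gates the observed
#' score.
#'
#' @inheritParams windowLogMarginal
#' @param n_boot permutation count (default 1000; values below 20 are
#'   refused as the percentile would be meaningless)
#' @param seed integer seed
#' @return list(boot_p95, draws)
#' @export
bootstrapNullPLO <- function(y, g, prior = treePrior(), n_boot = 1000,
                             seed) {
  if (n_boot < 20) stop("n_boot below 20: 95th percentile meaningless")
  if (missing(seed)) stop("seed is mandatory")
  y <- as.integer(y)
  if (is.null(dim(g))) g <- matrix(g, ncol = 1)
  masks <- .splitMasks(g)
  lm_null <- .leafLogMarginal(sum(y), length(y) - sum(y))
  set.seed(seed)
  Y <- vapply(seq_len(n_boot), function(b) sample(y), integer(length(y)))
  draws <- (cpp_grow_tree_multi(Y, masks$M0, masks$M1, prior$max_depth,
                                prior$min_leaf, prior$log_split_prior) -
              lm_null) / log(10)
  list(boot_p95 = unname(quantile(draws, 0.95, type = 7)), draws = draws)
}

#' Sliding-window grid over a variant map
#'
#' Tiles each chromosome from its first variant position in steps of
#' \code{step_bp} with windows of \code{window_bp}; windows containing no
#' SNP are dropped.  Each emitted window records its SNP index range into
#' the (sorted) variant table.
#'
#' @param variants data.frame from [variantInfo()] (sorted by chrom, pos)
#' @param window_bp window length in base pairs (default 100000)
#' @param step_bp slide step (default 50000; must be in (0, window_bp])
#' @return \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{n_snps}, \code{snp_first}, \code{snp_last} (row indices into
#'   \code{variants})
#' @export
makeWindows <- function(variants, window_bp = 100000, step_bp = 50000) {
  stopifnot(step_bp > 0, step_bp <= window_bp)
  w_chr <- character(); w_start <- numeric()
  w_n <- w_first <- w_last <- integer()
  for (chr in unique(variants$chrom)) {
    idx <- which(variants$chrom == chr)
    pos <- variants$pos[idx]
    for (s in seq(min(pos), max(pos), by = step_bp)) {
      inw <- idx[pos >= s & pos <= s + window_bp - 1]
      if (!length(inw)) next
      w_chr <- c(w_chr, chr); w_start <- c(w_start, s)
      w_n <- c(w_n, length(inw))
      w_first <- c(w_first, min(inw)); w_last <- c(w_last, max(inw))
    }
  }
  if (!length(w_chr)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(n_snps = integer(),
                                                 snp_first = integer(),
                                                 snp_last = integer())
    return(gr)
  }
  gr <- GenomicRanges::GRanges(w_chr,
          IRanges::IRanges(start = w_start, end = w_start + window_bp - 1))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    n_snps = w_n, snp_first = w_first, snp_last = w_last)
  gr
}

#' Screen one study over a window grid
#'
#' Computes the PLO for every window; windows at or above
#' \code{boot_plo_min} (when \code{n_boot > 0}) additionally get a
#' permutation-null 95th percentile.  The X chromosome is excluded when
#' \code{sex_stratum = "combined"}: the tree model does not compensate for
#' the male/female dosage difference there.
#'
#' @param study a \linkS4class{StudyGenotypes}
#' @param windows [makeWindows()] output (shared across studies)
#' @param prior [treePrior()]
#' @param n_boot permutations for the null gate (0 = skip; default 0, the
#'   pipeline bootstraps only pre-selected windows)
#' @param boot_plo_min only windows with plo >= this get a bootstrap
#'   (default 2)
#' @param sex_stratum "combined", "male" or "female"; non-combined strata
#'   subset the samples
#' @param seed integer seed (required when n_boot > 0)
#' @return data.frame chrom, start, end, n_snps, plo, boot_p95, boot_n
#' @export
screenStudy <- function(study, windows, prior = treePrior(), n_boot = 0,
                        boot_plo_min = 2, sex_stratum = "combined",
                        seed = NULL) {
  si <- sampleInfo(study)
  keep <- if (sex_stratum == "combined") rep(TRUE, nrow(si))
          else si$sex == sex_stratum
  y <- as.integer(si$phenotype[keep] == "case")
  G <- dosage(study)[keep, , drop = FALSE]
  chroms <- as.character(GenomicRanges::seqnames(windows))
  xchr <- chroms %in% c("X", "23", "chrX")
  mc <- S4Vectors::mcols(windows)
  n_w <- length(windows)
  plo <- rep(NA_real_, n_w)
  b95 <- rep(NA_real_, n_w)
  for (w in seq_len(n_w)) {
    if (sex_stratum == "combined" && xchr[w]) next
    g <- G[, mc$snp_first[w]:mc$snp_last[w], drop = FALSE]
    plo[w] <- windowPLO(y, g, prior)$plo
  }
  if (n_boot > 0) {
    if (is.null(seed)) stop("seed required when n_boot > 0")
    for (w in which(!is.na(plo) & plo >= boot_plo_min)) {
      g <- G[, mc$snp_first[w]:mc$snp_last[w], drop = FALSE]
      b95[w] <- bootstrapNullPLO(y, g, prior, n_boot,
                                 seed = seed + w)$boot_p95
    }
  }
  data.frame(chrom = chroms, start = GenomicRanges::start(windows),
             end = GenomicRanges::end(windows), n_snps = mc$n_snps,
             plo = plo, boot_p95 = b95,
             boot_n = ifelse(is.na(b95), 0L, as.integer(n_boot)),
             stringsAsFactors = FALSE)
}

#' Multi-study concordance selection of candidate regions
#'
#' Step A: windows whose PLO is at least \code{plo_min} in at least
#' \code{min_studies} studies of the same stratum.  Step B (when
#' \code{check_boot}): among those, keep windows whose PLO strictly
#' exceeds its permutation-null 95th percentile in every qualifying study.
#' Contiguous or overlapping qualifying windows merge into one candidate
#' region.
#'
#' @param plo_tables list of [screenStudy()] tables on an identical window
#'   grid
#' @param plo_min PLO threshold (default 2)
#' @param min_studies concordance requirement (default 2)
#' @param check_boot apply the bootstrap gate (default TRUE)
#' @return \link[GenomicRanges]{GRanges} of merged candidate regions with
#'   metadata column \code{n_windows}
#' @export
concordanceSelect <- function(plo_tables, plo_min = 2, min_studies = 2,
                              check_boot = TRUE) {
  stopifnot(length(plo_tables) >= min_studies)
  ref <- plo_tables[[1]][, c("chrom", "start", "end")]
  for (tb in plo_tables[-1])
    if (!identical(tb[, c("chrom", "start", "end")], ref))
      stop("window grids differ between studies")
  plo_mat <- sapply(plo_tables, `[[`, "plo")
  b95_mat <- sapply(plo_tables, `[[`, "boot_p95")
  if (is.null(dim(plo_mat))) {
    plo_mat <- matrix(plo_mat, nrow = 1)
    b95_mat <- matrix(b95_mat, nrow = 1)
  }
  qual <- !is.na(plo_mat) & plo_mat >= plo_min
  hit <- rowSums(qual) >= min_studies
  if (check_boot) {
    pass_boot <- !is.na(b95_mat) & plo_mat > b95_mat
    ok_boot <- rowSums(qual & pass_boot) == rowSums(qual)
    hit <- hit & ok_boot
  }
  if (!any(hit)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$n_windows <- integer()
    return(gr)
  }
  sel <- GenomicRanges::GRanges(ref$chrom[hit],
           IRanges::IRanges(start = ref$start[hit], end = ref$end[hit]))
  merged <- GenomicRanges::reduce(sel)
  ov <- GenomicRanges::countOverlaps(merged, sel)
  S4Vectors::mcols(merged)$n_windows <- ov
  S4Vectors::mcols(merged)$label <- paste0(
    as.character(GenomicRanges::seqnames(merged)), ":",
    GenomicRanges::start(merged), "-", GenomicRanges::end(merged))
  merged
}

#' Write a PLO track as bedGraph
#'
#' One line per window (0-based half-open on disk), value = PLO; loadable
#' in a genome browser for visual inspection of the screen.
#'
#' @param plo_table [screenStudy()] output
#' @param path output file
#' @param name track name
#' @return \code{path}, invisibly
#' @export
writePloTrack <- function(plo_table, path, name = "PLO") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  tb <- plo_table[!is.na(plo_table$plo), , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%.4f", tb$chrom, tb$start - 1L, tb$end,
                     tb$plo), con)
  invisible(path)
}
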