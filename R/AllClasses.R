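#' @import methods
#' @useDynLib regionwas, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowRanges colData
#' @importFrom S4Vectors mcols DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end reduce
#'   countOverlaps
#' @importFrom IRanges IRanges
#' @importFrom stats pnorm qnorm dbinom rbinom runif rnorm glm glm.fit
#'   binomial quantile sd median mad cor fisher.test coef vcov setNames
#'   complete.cases model.matrix plogis qlogis qbeta rbeta
#' @importFrom utils read.table write.table head tail
NULL

#' StudyGenotypes: hard-called genotypes for one case-control study
#'
#' A container for a single study's hard-called genotype dosages together
#' with variant and sample metadata.  It extends
#' \linkS4class{RangedSummarizedExperiment}: variants are rows (a
#' \link[GenomicRanges]{GRanges} with metadata columns \code{vid},
#' \code{a1}, \code{a2}), samples are columns (a \link[S4Vectors]{DataFrame}
#' with \code{sid}, \code{phenotype}, \code{sex}, \code{age}, \code{study}),
#' and the single assay \code{"dosage"} holds effect-allele counts in
#' \{0, 1, 2, NA\} with \code{NA} meaning a missing genotype call.
#'
#' The effect allele is \code{a1} (the PLINK bim A1 allele) throughout;
#' no strand flipping is ever attempted.  Missing dosages stay \code{NA}
#' and are only mean-imputed where a method's documentation says so.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}; no extra slots.
#' @seealso [StudyGenotypes()], [readPlink()], [writePlink()]
#' @export
setClass("StudyGenotypes", contains = "RangedSummarizedExperiment")

.validStudyGenotypes <- function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  rr <- SummarizedExperiment::rowRanges(object)
  mc <- S4Vectors::mcols(rr)
  need_v <- c("vid", "a1", "a2")
  miss <- setdiff(need_v, colnames(mc))
  if (length(miss))
    msg <- c(msg, paste0("rowRanges lacks column(s): ",
                         paste(miss, collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  need_s <- c("sid", "phenotype", "sex")
  miss <- setdiff(need_s, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if (!length(msg)) {
    ## spot-check the dosage alphabet on a bounded stretch; the
    ## constructor scans the full matrix once (validity runs many times
    ## during SummarizedExperiment assembly, so it must stay cheap)
    d <- SummarizedExperiment::assay(object, "dosage")
    probe <- d[seq_len(min(length(d), 10000L))]
    if (any(!is.na(probe) & (probe < 0 | probe > 2 | probe != floor(probe))))
      msg <- c(msg, "dosage entries must be 0, 1, 2 or NA")
    if (anyDuplicated(mc$vid))
      msg <- c(msg, "variant ids must be unique within a study")
    if (nrow(object) > 1) {
      o <- order(as.character(GenomicRanges::seqnames(rr)),
                 GenomicRanges::start(rr))
      if (!identical(o, seq_len(nrow(object))))
        msg <- c(msg, "variants must be sorted by (chrom, pos)")
    }
    if (any(mc$a1 == mc$a2))
      msg <- c(msg, "a1 and a2 must differ")
    ph <- cd$phenotype
    if (!all(ph %in% c("case", "control")))
      msg <- c(msg, "phenotype must be 'case' or 'control'")
    sx <- cd$sex
    if (!all(sx %in% c("male", "female")))
      msg <- c(msg, "sex must be 'male' or 'female'")
  }
  if (length(msg)) msg else TRUE
}

S4Vectors::setValidity2("StudyGenotypes", .validStudyGenotypes)

#' Construct a StudyGenotypes object
#'
#' @param dosage integer matrix, samples x variants (the orientation of the
#'   on-disk PLINK layout); entries 0/1/2 count copies of the effect allele
#'   \code{a1}, \code{NA} is a missing call.  It is transposed internally to
#'   the variants x samples orientation of SummarizedExperiment.
#' @param variants data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{vid}, \code{a1}, \code{a2}, one row per variant, in dosage column
#'   order.  Rows are re-sorted by (chrom, pos) together with the matrix.
#' @param samples data.frame with columns \code{sid}, \code{phenotype}
#'   ("case"/"control"), \code{sex} ("male"/"female"), and optionally
#'   \code{age} (years) and \code{study}, one row per sample.
#' @return a \linkS4class{StudyGenotypes}
#' @examples
#' sg <- StudyGenotypes(
#'   dosage   = matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3),
#'   variants = data.frame(chrom = "1", pos = c(100L, 200L),
#'                         vid = c("v1", "v2"), a1 = "A", a2 = "G"),
#'   samples  = data.frame(sid = paste0("s", 1:3),
#'                         phenotype = c("case", "control", "case"),
#'                         sex = c("male", "female", "male"), age = 50))
#' dim(sg)
#' @export
StudyGenotypes <- function(dosage, variants, samples) {
  stopifnot(is.matrix(dosage),
            nrow(dosage) == nrow(samples),
            ncol(dosage) == nrow(variants))
  if (is.null(variants$vid)) stop("variants$vid is required")
  ## full alphabet scan happens once, here
  rng <- suppressWarnings(range(dosage, na.rm = TRUE))
  if (is.finite(rng[1]) &&
      (rng[1] < 0 || rng[2] > 2 ||
       (!is.integer(dosage) && any(dosage != floor(dosage), na.rm = TRUE))))
    stop("dosage entries must be 0, 1, 2 or NA")
  o <- order(as.character(variants$chrom), variants$pos)
  variants <- variants[o, , drop = FALSE]
  dosage <- dosage[, o, drop = FALSE]
  dimnames(dosage) <- NULL
  if (nrow(variants)) {
    rr <- GenomicRanges::GRanges(
      seqnames = as.character(variants$chrom),
      ranges = IRanges::IRanges(start = as.integer(variants$pos), width = 1L),
      vid = as.character(variants$vid),
      a1 = as.character(variants$a1),
      a2 = as.character(variants$a2))
  } else {
    rr <- GenomicRanges::GRanges()
    S4Vectors::mcols(rr) <- S4Vectors::DataFrame(vid = character(),
                                                 a1 = character(),
                                                 a2 = character())
  }
  names(rr) <- S4Vectors::mcols(rr)$vid
  cd <- S4Vectors::DataFrame(
    sid = as.character(samples$sid),
    phenotype = as.character(samples$phenotype),
    sex = as.character(samples$sex))
  cd$age <- if (is.null(samples$age)) NA_real_ else as.numeric(samples$age)
  cd$study <- if (is.null(samples$study)) NA_character_
              else as.character(samples$study)
  rownames(cd) <- cd$sid
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dosage)), rowRanges = rr, colData = cd)
  new("StudyGenotypes", se)
}

#' @describeIn StudyGenotypes compact display
#' @param object a StudyGenotypes
#' @export
setMethod("show", "StudyGenotypes", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("StudyGenotypes:", nrow(object), "variants x", ncol(object),
      "samples\n")
  cat("  cases:", sum(cd$phenotype == "case"),
      " controls:", sum(cd$phenotype == "control"),
      " (male:", sum(cd$sex == "male"),
      ", female:", sum(cd$sex == "female"), ")\n")
  d <- SummarizedExperiment::assay(object, "dosage")
  cat("  missing dosage:",
      sprintf("%.2f%%", 100 * mean(is.na(d))), "\n")
  invisible(NULL)
})

#' Dosage matrix accessor
#'
#' Returns the genotype dosages of a \linkS4class{StudyGenotypes} as a
#' samples x variants numeric matrix (0/1/2 copies of the effect allele,
#' \code{NA} missing), with sample ids as row names and variant ids as
#' column names.
#'
#' @param x a StudyGenotypes
#' @return numeric matrix, samples x variants
#' @export
dosage <- function(x) {
  stopifnot(is(x, "StudyGenotypes"))
  d <- t(SummarizedExperiment::assay(x, "dosage"))
  rownames(d) <- SummarizedExperiment::colData(x)$sid
  colnames(d) <- S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$vid
  d
}

#' Variant metadata accessor
#'
#' @param x a StudyGenotypes
#' @return data.frame with columns chrom, pos, vid, a1, a2 (one row per
#'   variant, sorted by chrom then position)
#' @export
variantInfo <- function(x) {
  stopifnot(is(x, "StudyGenotypes"))
  rr <- SummarizedExperiment::rowRanges(x)
  mc <- S4Vectors::mcols(rr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             vid = mc$vid, a1 = mc$a1, a2 = mc$a2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sample metadata accessor
#'
#' @param x a StudyGenotypes
#' @return data.frame with columns sid, phenotype, sex, age, study
#' @export
sampleInfo <- function(x) {
  stopifnot(is(x, "StudyGenotypes"))
  as.data.frame(SummarizedExperiment::colData(x))
}

#' HaplotypePool: a phased binary haplotype panel with LD blocks
#'
#' Haplotypes generated by a within-block copying process; the panel is the
#' shared ancestral pool that parallel case-control studies draw diploid
#' genotypes from.
#'
#' @slot haplotypes H x M binary (0/1) matrix, one row per haplotype.
#' @slot blocks integer vector of length M assigning each SNP to an LD block.
#' @slot maf numeric vector of realized allele-1 frequencies per SNP.
#' @slot pos integer vector of base-pair positions (1-based) per SNP.
#' @slot chrom chromosome label shared by all SNPs in the pool.
#' @seealso [buildHaplotypePool()], [simulateStudy()]
#' @export
setClass("HaplotypePool",
         representation(haplotypes = "matrix", blocks = "integer",
                        maf = "numeric", pos = "integer",
                        chrom = "character"))

setValidity("HaplotypePool", function(object) {
  msg <- character()
  h <- object@haplotypes
  if (!all(h %in% c(0L, 1L))) msg <- c(msg, "haplotypes must be 0/1")
  if (length(object@blocks) != ncol(h))
    msg <- c(msg, "blocks length must equal SNP count")
  if (length(object@maf) != ncol(h))
    msg <- c(msg, "maf length must equal SNP count")
  if (length(object@pos) != ncol(h))
    msg <- c(msg, "pos length must equal SNP count")
  if (length(msg)) msg else TRUE
})

#' @describeIn HaplotypePool compact display
#' @param object a HaplotypePool
#' @export
setMethod("show", "HaplotypePool", function(object) {
  cat("HaplotypePool:", nrow(object@haplotypes), "haplotypes x",
      ncol(object@haplotypes), "SNPs in",
      length(unique(object@blocks)), "LD blocks\n")
  cat("  MAF range:", sprintf("[%.3f, %.3f]",
      min(pmin(object@maf, 1 - object@maf)),
      max(pmin(object@maf, 1 - object@maf))), "\n")
  invisible(NULL)
})
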