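## PLINK v1.0 binary genotype triple (bed/bim/fam), SNP-major layout.
## Two-bit codes per sample, least-significant pair first within a byte:
##   00 = homozygous A1 (2 effect-allele copies), 01 = missing,
##   10 = heterozygous (1 copy), 11 = homozygous A2 (0 copies).

.BED_MAGIC <- as.raw(c(0x6c, 0x1b))
.SNP_MAJOR <- as.raw(0x01)

## dosage value for each 2-bit code 0..3
.BED_CODE_TO_DOSAGE <- c(2L, NA_integer_, 1L, 0L)

#' Read a PLINK bed/bim/fam genotype triple
#'
#' Reads hard-called genotypes in the PLINK v1.0 binary format (magic bytes
#' \code{0x6C 0x1B}, third byte \code{0x01} for SNP-major order).  Dosages
#' count copies of the bim A1 allele, which is the effect allele everywhere
#' in this package; the missing code is preserved as \code{NA}.
#'
#' fam columns follow the PLINK convention: sex 1 = male, 2 = female;
#' phenotype 1 = control, 2 = case.  Any other phenotype/sex code becomes a
#' missing value and the sample is rejected by the container's validity
#' check, which keeps silent coercion out of the pipeline.
#'
#' @param prefix path stem; \code{<prefix>.bed/.bim/.fam} must all exist.
#' @return a \linkS4class{StudyGenotypes}
#' @export
readPlink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  ok <- file.exists(paths)
  if (!all(ok))
    stop("missing file(s): ", paste(paths[!ok], collapse = ", "))
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "vid", "cm", "pos", "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "sid", "pat", "mat", "sexcode",
                                  "phencode"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || !identical(raw[1:2], .BED_MAGIC))
    stop("not a PLINK bed file (bad magic bytes): ", paths[1])
  if (!identical(raw[3], .SNP_MAJOR))
    stop("bed file is not SNP-major (third byte != 0x01): ", paths[1])
  bpv <- ceiling(n / 4)            # bytes per variant
  payload <- raw[-(1:3)]
  if (length(payload) != bpv * m)
    stop("bed payload size (", length(payload),
         " bytes) inconsistent with fam/bim dimensions (expected ",
         bpv * m, ")")
  dos <- matrix(NA_integer_, nrow = n, ncol = m)
  if (m > 0 && n > 0) {
    bytes <- as.integer(payload)
    dim(bytes) <- c(bpv, m)
    idx <- seq_len(n)
    byte_of <- ((idx - 1L) %/% 4L) + 1L
    shift <- 2L * ((idx - 1L) %% 4L)
    for (s in 0:3) {
      sel <- shift == 2L * s
      if (!any(sel)) next
      codes <- (bytes[byte_of[sel], , drop = FALSE] %/% 4L^s) %% 4L
      dos[idx[sel], ] <- .BED_CODE_TO_DOSAGE[codes + 1L]
    }
  }
  samples <- data.frame(
    sid = as.character(fam$sid),
    phenotype = c("control", "case")[match(fam$phencode, c(1, 2))],
    sex = c("male", "female")[match(fam$sexcode, c(1, 2))],
    age = NA_real_,
    study = NA_character_,
    stringsAsFactors = FALSE)
  StudyGenotypes(dosage = dos, variants = bim[, c("chrom", "pos", "vid",
                                                  "a1", "a2")],
                 samples = samples)
}

#' Write a StudyGenotypes to a PLINK bed/bim/fam triple
#'
#' Inverse of [readPlink()]: \code{readPlink(writePlink(x, p))} reproduces
#' the dosage matrix and metadata exactly (ages and study labels are not
#' representable in fam and are dropped).
#'
#' @param study a \linkS4class{StudyGenotypes}
#' @param prefix output path stem
#' @return \code{prefix}, invisibly
#' @export
writePlink <- function(study, prefix) {
  stopifnot(is(study, "StudyGenotypes"))
  vi <- variantInfo(study)
  si <- sampleInfo(study)
  dos <- dosage(study)
  n <- nrow(dos)
  m <- ncol(dos)
  bim <- data.frame(vi$chrom, vi$vid, rep(0, m), vi$pos, vi$a1, vi$a2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(si$sid, si$sid, 0, 0,
                    ifelse(si$sex == "male", 1L, 2L),
                    ifelse(si$phenotype == "case", 2L, 1L))
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bpv <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(.BED_MAGIC, .SNP_MAJOR), con)
  if (m > 0) {
    ## dosage -> 2-bit code: 2->00, NA->01, 1->10, 0->11
    code <- matrix(3L, nrow = n, ncol = m)
    code[is.na(dos)] <- 1L
    code[!is.na(dos) & dos == 1] <- 2L
    code[!is.na(dos) & dos == 2] <- 0L
    pad <- bpv * 4L - n
    if (pad > 0)          # pad samples encode as missing-free zeros
      code <- rbind(code, matrix(0L, nrow = pad, ncol = m))
    w <- 4L^(0:3)
    grp <- matrix(0L, nrow = bpv, ncol = m)
    for (s in 1:4)
      grp <- grp + code[seq(s, nrow(code), by = 4L), , drop = FALSE] *
        w[s]
    writeBin(as.raw(grp), con)
  }
  invisible(prefix)
}

#' Is a variant strand-ambiguous?
#'
#' A/T and C/G variants cannot be strand-resolved from alleles alone; they
#' are flagged (never removed) so that attenuation from unresolved strands
#' in aggregated analyses stays observable.
#'
#' @param a1,a2 allele character vectors
#' @return logical vector
#' @export
isStrandAmbiguous <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  unname(!is.na(comp[toupper(a1)]) & comp[toupper(a1)] == toupper(a2))
}

.SUMSTAT_COLS <- c("chrom", "pos", "vid", "a1", "a2", "beta", "se", "p",
                   "n_case", "n_ctrl")

#' Read a per-SNP summary-statistics table
#'
#' Tab-separated with header columns \code{chrom, pos, vid, a1, a2, beta,
#' se, p, n_case, n_ctrl}; \code{beta} is the log-odds effect of allele
#' \code{a1}.  Rows violating the invariants (\code{se <= 0}, \code{p}
#' outside (0, 1], non-numeric fields, or \code{p} inconsistent with
#' \code{|beta/se|} by more than a factor-2 band on the z scale) are
#' skipped; the number skipped is reported via a message and in attribute
#' \code{"n_skipped"}.
#'
#' @param path TSV file
#' @param check_p_consistency verify p against the Wald z within a printing
#'   tolerance (default TRUE)
#' @return data.frame sorted by (chrom, pos) with an extra logical column
#'   \code{ambiguous} flagging A/T / C/G variants
#' @export
readSummaryStats <- function(path, check_p_consistency = TRUE) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  miss <- setdiff(.SUMSTAT_COLS, names(df))
  if (length(miss))
    stop("summary-stats file lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  df <- df[, .SUMSTAT_COLS]
  for (nm in c("pos", "beta", "se", "p", "n_case", "n_ctrl"))
    df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  ok <- complete.cases(df[, c("pos", "beta", "se", "p")]) &
    df$se > 0 & df$p > 0 & df$p <= 1
  if (check_p_consistency) {
    ## printed p must agree with |beta/se| up to rounding: compare on the
    ## z scale with a generous band so 2-decimal ORs survive
    zp <- qnorm(pmin(df$p, 1 - 1e-16) / 2, lower.tail = FALSE)
    zb <- abs(df$beta / df$se)
    ok <- ok & (is.na(zp) | abs(zp - zb) <= 0.2 + 0.05 * zb)
  }
  ok[is.na(ok)] <- FALSE
  n_skipped <- sum(!ok)
  if (n_skipped)
    message(n_skipped, " malformed summary-stat row(s) skipped")
  df <- df[ok, , drop = FALSE]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df$ambiguous <- isStrandAmbiguous(df$a1, df$a2)
  attr(df, "n_skipped") <- n_skipped
  df
}

#' Write a summary-statistics table
#'
#' @param stats data.frame in [readSummaryStats()] layout
#' @param path output TSV
#' @return \code{path}, invisibly
#' @export
writeSummaryStats <- function(stats, path) {
  write.table(stats[, .SUMSTAT_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a BED region list
#'
#' 3+ column BED, 0-based half-open on disk; converted to the 1-based
#' closed coordinates of \link[GenomicRanges]{GRanges} on input.  Column 4,
#' when present, becomes the region label; otherwise labels default to
#' \code{"chrom:start-end"} (BED coordinates).  Overlapping regions are
#' retained as-is, never merged.
#'
#' @param path BED file
#' @return \link[GenomicRanges]{GRanges} with metadata column \code{label}
#' @export
readRegionsBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$label <- character()
    return(gr)
  }
  parts <- strsplit(lines, "[ \t]+")
  ncols <- vapply(parts, length, integer(1))
  if (any(ncols < 3))
    stop("BED row(s) with fewer than 3 columns: line(s) ",
         paste(which(ncols < 3), collapse = ", "))
  chrom <- vapply(parts, `[[`, character(1), 1)
  start0 <- as.numeric(vapply(parts, `[[`, character(1), 2))
  end0 <- as.numeric(vapply(parts, `[[`, character(1), 3))
  if (anyNA(start0) || anyNA(end0))
    stop("non-numeric BED coordinates")
  bad <- start0 >= end0
  if (any(bad))
    stop("BED row(s) with start >= end: line(s) ",
         paste(which(bad), collapse = ", "))
  label <- ifelse(ncols >= 4, vapply(parts, function(p)
    if (length(p) >= 4) p[[4]] else "", character(1)),
    paste0(chrom, ":", format(start0, scientific = FALSE, trim = TRUE),
           "-", format(end0, scientific = FALSE, trim = TRUE)))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start0) + 1L,
                              end = as.integer(end0)))
  S4Vectors::mcols(gr)$label <- label
  gr
}

#' Build a GRanges region from 1-based closed coordinates
#'
#' Convenience constructor used throughout: \code{region("1", 100, 200)}.
#'
#' @param chrom chromosome label
#' @param start,end 1-based closed base-pair bounds, start <= end
#' @param label optional locus name
#' @return single-range \link[GenomicRanges]{GRanges} with \code{label}
#' @export
region <- function(chrom, start, end, label = NULL) {
  stopifnot(start <= end)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start, end = end))
  S4Vectors::mcols(gr)$label <-
    if (is.null(label)) paste0(chrom, ":", start, "-", end) else label
  gr
}

## variant indices of `study` falling in `reg` (single range)
.variantsInRegion <- function(study, reg) {
  vi <- variantInfo(study)
  which(vi$chrom == as.character(GenomicRanges::seqnames(reg))[1] &
          vi$pos >= GenomicRanges::start(reg)[1] &
          vi$pos <= GenomicRanges::end(reg)[1])
}

## subset a StudyGenotypes, preserving class
.subsetStudy <- function(study, variant_idx = NULL, sample_idx = NULL) {
  if (is.null(variant_idx)) variant_idx <- seq_len(nrow(study))
  if (is.null(sample_idx)) sample_idx <- seq_len(ncol(study))
  out <- study[variant_idx, sample_idx]
  new("StudyGenotypes", out)
}
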