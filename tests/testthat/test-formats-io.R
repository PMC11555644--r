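test_that("PLINK round-trip preserves dosage, metadata and missingness", {
  for (seed in 1:25) {
    st <- randomStudy(n = sample(3:12, 1), m = sample(1:15, 1),
                      seed = seed, miss = 0.1)
    prefix <- file.path(withr::local_tempdir(), "rt")
    writePlink(st, prefix)
    st2 <- readPlink(prefix)
    expect_identical(dosage(st), dosage(st2))
    expect_identical(variantInfo(st), variantInfo(st2))
    expect_identical(sampleInfo(st)[, c("sid", "phenotype", "sex")],
                     sampleInfo(st2)[, c("sid", "phenotype", "sex")])
  }
  ## double round-trip is byte-identical
  st <- randomStudy(n = 20, m = 50, seed = 99)
  d <- withr::local_tempdir()
  writePlink(st, file.path(d, "a"))
  writePlink(readPlink(file.path(d, "a")), file.path(d, "b"))
  for (ext in c(".bed", ".bim", ".fam"))
    expect_identical(readBin(file.path(d, paste0("a", ext)), "raw", 1e5),
                     readBin(file.path(d, paste0("b", ext)), "raw", 1e5))
})

test_that("bed two-bit decoding follows the PLINK v1.0 code table", {
  ## byte 0b11100100: samples (low bits first) 00,01,10,11
  ##   -> hom A1 = 2 copies, missing, het = 1, hom A2 = 0
  d <- withr::local_tempdir()
  con <- file(file.path(d, "x.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xE4)), con)
  close(con)
  writeLines("1\tv1\t0\t100\tA\tG", file.path(d, "x.bim"))
  writeLines(sprintf("f%d\ts%d\t0\t0\t1\t1", 1:4, 1:4),
             file.path(d, "x.fam"))
  st <- readPlink(file.path(d, "x"))
  expect_identical(unname(dosage(st)[, 1]), c(2L, NA, 1L, 0L))
})

test_that("malformed bed files are rejected", {
  d <- withr::local_tempdir()
  writeLines("1\tv1\t0\t100\tA\tG", file.path(d, "x.bim"))
  writeLines("f1\ts1\t0\t0\t1\t1", file.path(d, "x.fam"))
  con <- file(file.path(d, "x.bed"), "wb")
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), con); close(con)
  expect_error(readPlink(file.path(d, "x")), "magic")
  ## dimension mismatch: 2 variants claimed, payload for 1
  writeLines(c("1\tv1\t0\t100\tA\tG", "1\tv2\t0\t200\tA\tG"),
             file.path(d, "x.bim"))
  con <- file(file.path(d, "x.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00)), con); close(con)
  expect_error(readPlink(file.path(d, "x")), "inconsistent")
})

test_that("empty-variant study writes a valid zero-SNP triple", {
  st <- StudyGenotypes(
    dosage = matrix(integer(), nrow = 3, ncol = 0),
    variants = data.frame(chrom = character(), pos = integer(),
                          vid = character(), a1 = character(),
                          a2 = character()),
    samples = data.frame(sid = paste0("s", 1:3),
                         phenotype = c("case", "control", "case"),
                         sex = "male", age = 50))
  prefix <- file.path(withr::local_tempdir(), "empty")
  writePlink(st, prefix)
  st2 <- readPlink(prefix)
  expect_equal(nrow(st2), 0)
  expect_equal(ncol(st2), 3)
})

test_that("summary-stats reader enforces the schema and row invariants", {
  d <- withr::local_tempdir()
  f <- file.path(d, "ss.tsv")
  ## AGOG male rs35042965 published row: beta/se recovered from OR/CI
  bc <- betaFromOrCi(0.75, 0.58, 0.97)
  rows <- data.frame(
    chrom = c("1", "1", "2"), pos = c(14184325, 99, 50),
    vid = c("rs35042965", "bad_se", "null_snp"),
    a1 = "A", a2 = "G",
    beta = c(bc$beta, 0.5, 0), se = c(bc$se, -1, 0.2),
    p = c(0.0285, 0.5, 1), n_case = 346, n_ctrl = 962)
  write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(ss <- readSummaryStats(f), "1 malformed")
  expect_equal(attr(ss, "n_skipped"), 1)        # se <= 0 skipped
  expect_setequal(ss$vid, c("rs35042965", "null_snp"))
  ## printed p consistent with recomputed Wald p
  z_row <- abs(ss$beta[ss$vid == "rs35042965"] /
                 ss$se[ss$vid == "rs35042965"])
  expect_lt(abs(z_row - abs(qnorm(0.0285 / 2))), 0.05)
  ## beta = 0 with p = 1 passes the consistency band
  expect_true("null_snp" %in% ss$vid)
  ## missing mandatory column
  write.table(rows[, -6], f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(readSummaryStats(f), "mandatory")
})

test_that("BED regions are converted, labelled and never merged", {
  d <- withr::local_tempdir()
  f <- file.path(d, "r.bed")
  writeLines(c("16\t7000000\t7400000\t16p13.3",
               "1\t100\t200",
               "1\t150\t250"), f)
  gr <- readRegionsBed(f)
  expect_equal(length(gr), 3)
  i <- which(S4Vectors::mcols(gr)$label == "16p13.3")
  expect_equal(GenomicRanges::width(gr)[i], 400000)
  expect_equal(GenomicRanges::start(gr)[i], 7000001)  # 1-based internal
  ## unlabelled rows get chrom:start-end labels; overlaps retained
  expect_equal(sum(S4Vectors::mcols(gr)$label == "1:100-200"), 1)
  expect_equal(sum(as.character(GenomicRanges::seqnames(gr)) == "1"), 2)
  ## empty file
  writeLines(character(), f)
  expect_equal(length(readRegionsBed(f)), 0)
  ## start >= end is a row error
  writeLines("1\t500\t500", f)
  expect_error(readRegionsBed(f), "start >= end")
})

test_that("strand-ambiguous variants are flagged, not removed", {
  expect_identical(isStrandAmbiguous(c("A", "C", "A", "G"),
                                     c("T", "G", "G", "C")),
                   c(TRUE, TRUE, FALSE, TRUE))
  d <- withr::local_tempdir()
  f <- file.path(d, "ss.tsv")
  write.table(data.frame(chrom = "1", pos = 1:2, vid = c("a", "b"),
                         a1 = c("A", "A"), a2 = c("T", "G"),
                         beta = 0, se = 1, p = 1,
                         n_case = 10, n_ctrl = 10),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- readSummaryStats(f)
  expect_identical(ss$ambiguous, c(TRUE, FALSE))
  expect_equal(nrow(ss), 2)
})

test_that("container invariants reject bad inputs instead of coercing", {
  expect_error(StudyGenotypes(
    dosage = matrix(3L, 1, 1),
    variants = data.frame(chrom = "1", pos = 1, vid = "v", a1 = "A",
                          a2 = "G"),
    samples = data.frame(sid = "s", phenotype = "case", sex = "male")),
    "dosage")
  expect_error(validObject(StudyGenotypes(
    dosage = matrix(1L, 1, 2),
    variants = data.frame(chrom = "1", pos = c(1, 2),
                          vid = c("v", "v"), a1 = "A", a2 = "G"),
    samples = data.frame(sid = "s", phenotype = "case",
                         sex = "male"))), "unique")
  expect_error(StudyGenotypes(
    dosage = matrix(1L, 1, 1),
    variants = data.frame(chrom = "1", pos = 1, vid = "v", a1 = "A",
                          a2 = "A"),
    samples = data.frame(sid = "s", phenotype = "case", sex = "male")),
    "a1 and a2")
})
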