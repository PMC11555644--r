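test_that("window grids tile from the first variant and drop empties", {
  ## SNPs spanning 250 kb at 1 kb spacing: 100 kb windows, 50 kb step
  v <- data.frame(chrom = "1", pos = seq(0, 250000, by = 1000) + 1L,
                  vid = paste0("v", 0:250), a1 = "A", a2 = "G")
  w <- makeWindows(v, 100000, 50000)
  expect_equal(length(w), 6)   # offsets 0..250 kb, all non-empty
  expect_equal(GenomicRanges::start(w),
               seq(1, 250001, by = 50000))
  ## SNPs only in [0, 249k]: the 250 kb window is empty and dropped
  v2 <- v[v$pos <= 249000, ]
  w2 <- makeWindows(v2, 100000, 50000)
  expect_equal(length(w2), 5)
  ## single SNP: at most 2 windows at 50% overlap
  w3 <- makeWindows(v[100, ], 100000, 50000)
  expect_lte(length(w3), 2)
  expect_true(all(S4Vectors::mcols(w3)$n_snps == 1))
  ## step = window: disjoint tiling, every SNP in exactly one window
  w4 <- makeWindows(v, 100000, 100000)
  mc <- S4Vectors::mcols(w4)
  covered <- unlist(lapply(seq_along(w4), function(i)
    mc$snp_first[i]:mc$snp_last[i]))
  expect_identical(sort(covered), seq_len(nrow(v)))
})

test_that("no-split tree equals the Beta-Binomial closed form", {
  ## 3 cases, 2 controls: ln B(4,3) = ln(1/60)
  y <- c(1, 1, 1, 0, 0)
  g <- matrix(0, 5, 1)
  expect_equal(windowLogMarginal(y, g), log(1 / 60))
  expect_equal(windowPLO(y, g)$plo, 0)
  expect_error(windowLogMarginal(rep(1, 5), g), "both classes")
})

test_that("a perfectly separating SNP wins a large marginal gain", {
  y <- rep(c(1L, 0L), each = 100)
  g <- matrix(c(rep(2L, 100), rep(0L, 100)), ncol = 1)
  null_lm <- lbeta(101, 101)
  expect_gt(windowLogMarginal(y, g) - null_lm, 20)
  expect_gt(windowPLO(y, g)$plo, 2)
})

test_that("PLO is invariant to sample order and label swap", {
  pool <- sharedPool()
  st <- simulateStudy(pool, 150, 150, seed = 103)
  y <- as.integer(sampleInfo(st)$phenotype == "case")
  g <- dosage(st)[, 1:20]
  p0 <- windowPLO(y, g)$plo
  perm <- sample(length(y))
  expect_equal(windowPLO(y[perm], g[perm, ])$plo, p0)
  ## Beta(1,1) leaves are symmetric in the class labels
  expect_equal(windowPLO(1L - y, g)$plo, p0)
})

test_that("null windows rarely reward a tree; effects raise the PLO", {
  pool <- sharedPool()
  ## null: a single-SNP window almost never accepts a split, and a
  ## 20-SNP window's tree marginal stays within a nat of the null
  ## marginal for most draws (split-candidate multiplicity allows an
  ## occasional small spurious gain)
  diffs <- vapply(1:20, function(s) {
    st <- simulateStudy(pool, 500, 500, seed = 400 + s)
    y <- as.integer(sampleInfo(st)$phenotype == "case")
    r1 <- windowPLO(y, dosage(st)[, 30, drop = FALSE])
    r20 <- windowPLO(y, dosage(st)[, 21:40])
    c(r1$log_marginal - r1$null_log_marginal,
      r20$log_marginal - r20$null_log_marginal)
  }, numeric(2))
  expect_gte(mean(diffs[1, ] < 1), 0.95)
  expect_gte(mean(diffs[2, ] < 1), 0.8)
  ## monotonicity: median PLO never decreases with the planted OR
  vids <- sprintf("snp%06d", seq_along(pool@maf))
  reg <- region("1", pool@pos[60] - 1, pool@pos[60] + 1)
  med <- vapply(c(1.0, 1.5, 2.2), function(or) {
    plos <- vapply(1:8, function(s) {
      ef <- if (or > 1) list(effectSpec(reg, vids[60], or)) else list()
      st <- simulateStudy(pool, 400, 400, effects = ef, seed = 500 + s)
      y <- as.integer(sampleInfo(st)$phenotype == "case")
      windowPLO(y, dosage(st)[, 51:70])$plo
    }, numeric(1))
    median(plos)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})

test_that("a strong effect clears the screen threshold reliably", {
  pool <- sharedPool()
  vids <- sprintf("snp%06d", seq_along(pool@maf))
  ## pick a common variant so the per-copy effect is visible
  j <- which.max(pmin(pool@maf, 1 - pool@maf))
  reg <- region("1", pool@pos[j] - 1, pool@pos[j] + 1)
  ef <- effectSpec(reg, vids[j], or_per_allele = 2.0)
  cols <- max(1, j - 10):min(length(vids), j + 10)
  hits <- vapply(1:20, function(s) {
    st <- simulateStudy(pool, 1000, 1000, effects = list(ef),
                        seed = 700 + s)
    y <- as.integer(sampleInfo(st)$phenotype == "case")
    windowPLO(y, dosage(st)[, cols])$plo > 2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("permutation null gate is reproducible and guarded", {
  pool <- sharedPool()
  st <- simulateStudy(pool, 200, 200, seed = 111)
  y <- as.integer(sampleInfo(st)$phenotype == "case")
  g <- dosage(st)[, 1:15]
  b1 <- bootstrapNullPLO(y, g, n_boot = 100, seed = 9)
  b2 <- bootstrapNullPLO(y, g, n_boot = 100, seed = 9)
  expect_identical(b1$boot_p95, b2$boot_p95)
  expect_length(b1$draws, 100)
  expect_error(bootstrapNullPLO(y, g, n_boot = 10, seed = 9), "20")
})

test_that("concordance selection applies the two-of-three rule", {
  grid <- data.frame(chrom = "1",
                     start = c(1, 50001, 100001),
                     end = c(100000, 150000, 200000))
  mk <- function(plo, b95) cbind(grid, plo = plo, boot_p95 = b95,
                                 boot_n = 1000L)
  ## only one study >= 2.0 in window 1 -> not selected
  t1 <- list(mk(c(2.1, 0.1, 0.2), c(1, 1, 1)),
             mk(c(1.9, 0.1, 0.2), c(1, 1, 1)),
             mk(c(0.3, 0.1, 0.2), c(1, 1, 1)))
  expect_length(concordanceSelect(t1), 0)
  ## two studies >= 2.0, both above their permutation gate -> selected
  t2 <- list(mk(c(2.1, 0.1, 0.2), c(1.0, 1, 1)),
             mk(c(2.5, 0.1, 0.2), c(1.2, 1, 1)),
             mk(c(0.3, 0.1, 0.2), c(1.0, 1, 1)))
  sel <- concordanceSelect(t2)
  expect_length(sel, 1)
  ## failing the gate in one qualifying study drops the window
  t3 <- list(mk(c(2.1, 0.1, 0.2), c(2.3, 1, 1)),
             mk(c(2.5, 0.1, 0.2), c(1.2, 1, 1)),
             mk(c(0.3, 0.1, 0.2), c(1.0, 1, 1)))
  expect_length(concordanceSelect(t3), 0)
  ## adjacent qualifying windows merge into one region
  t4 <- list(mk(c(2.1, 2.2, 0.2), c(1, 1, 1)),
             mk(c(2.5, 2.4, 0.2), c(1, 1, 1)),
             mk(c(0.3, 0.1, 0.2), c(1, 1, 1)))
  sel4 <- concordanceSelect(t4)
  expect_length(sel4, 1)
  expect_equal(S4Vectors::mcols(sel4)$n_windows, 2)
  expect_equal(GenomicRanges::width(sel4), 150000)
  ## mismatched grids are refused
  t5 <- t4
  t5[[2]]$start[1] <- 2
  expect_error(concordanceSelect(t5), "grids differ")
})

test_that("X chromosome is skipped for combined-sex screens only", {
  set.seed(131)
  n <- 120
  dos <- matrix(sample(0:2, n * 20, replace = TRUE), n, 20)
  storage.mode(dos) <- "integer"
  st <- StudyGenotypes(
    dos,
    data.frame(chrom = rep(c("1", "X"), each = 10),
               pos = rep(seq(1000, 10000, by = 1000), 2),
               vid = sprintf("v%02d", 1:20), a1 = "A", a2 = "G"),
    data.frame(sid = sprintf("s%03d", 1:n),
               phenotype = rep(c("case", "control"), n / 2),
               sex = rep(c("male", "female"), each = n / 2), age = 50))
  w <- makeWindows(variantInfo(st), 10000, 10000)
  tb_c <- screenStudy(st, w, sex_stratum = "combined")
  tb_m <- screenStudy(st, w, sex_stratum = "male")
  expect_true(all(is.na(tb_c$plo[tb_c$chrom == "X"])))
  expect_true(all(!is.na(tb_c$plo[tb_c$chrom == "1"])))
  expect_true(all(!is.na(tb_m$plo)))
})
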