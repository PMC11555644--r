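test_that("score z equals the Cochran-Armitage trend z without covariates", {
  pool <- sharedPool()
  st <- simulateStudy(pool, 200, 200, seed = 201)
  y <- as.integer(sampleInfo(st)$phenotype == "case")
  G <- dosage(st)
  ms <- marginalScores(st)
  for (j in c(1, 57, 213, 400)) {
    expect_equal(ms$z[j], trendTestZ(G[, j], y), tolerance = 1e-6)
  }
})

test_that("null scores are standard normal and duplicates share sigma 1", {
  pool <- fixture("pool500", function()
    buildHaplotypePool(800, 500, block_len = 10,
                       recomb_between_blocks = 0.5, mutation = 0.4,
                       seed = 31))
  st <- simulateStudy(pool, 400, 400, seed = 203)
  covs <- cbind(age = sampleInfo(st)$age,
                male = as.numeric(sampleInfo(st)$sex == "male"))
  ms <- marginalScores(st, covariates = covs)
  expect_lt(abs(mean(abs(ms$z)) - sqrt(2 / pi)), 0.06)
  expect_lt(abs(mean(ms$z)), 4 / sqrt(length(ms$z)))
  ## duplicated SNP column: perfect correlation in sigma
  G <- dosage(st)
  G[, 2] <- G[, 1]
  vi <- variantInfo(st)
  st2 <- StudyGenotypes(G, vi, sampleInfo(st)[, c("sid", "phenotype",
                                                  "sex", "age")])
  ms2 <- marginalScores(st2)
  expect_equal(ms2$sigma[1, 2], 1, tolerance = 1e-10)
})

test_that("LD pruning matches brute-force removal on small instances", {
  pool <- sharedPool()
  st <- simulateStudy(pool, 300, 300, seed = 205)
  vi <- variantInfo(st)
  ## 10-SNP regions, window larger than the block
  for (start_j in c(1, 101, 201)) {
    reg <- region("1", vi$pos[start_j], vi$pos[start_j + 9])
    kept <- ldPrune(st, reg, r2_max = 0.5, window_snps = 50)
    G <- dosage(st)[, start_j:(start_j + 9)]
    oracle <- brutePrune(G, 0.5) + start_j - 1L
    expect_identical(as.integer(kept), as.integer(oracle))
  }
  ## identical SNPs: exactly one survives
  G <- dosage(st)[, 1:5]
  G[, 2] <- G[, 1]
  st2 <- StudyGenotypes(G, vi[1:5, ],
                        sampleInfo(st)[, c("sid", "phenotype", "sex",
                                           "age")])
  kept2 <- ldPrune(st2, NULL)
  expect_equal(length(kept2), 4)
  ## already-independent set: identity
  p_ind <- buildHaplotypePool(400, 12, block_len = 2,
                              recomb_between_blocks = 0.5,
                              mutation = 0.4, seed = 207)
  st3 <- simulateStudy(p_ind, 200, 200, seed = 208)
  expect_length(ldPrune(st3, NULL), 12)
})

test_that("GBJ reduces to brute-force Berk-Jones under independence", {
  set.seed(211)
  for (i in 1:10) {
    d <- sample(c(3, 10, 25, 50), 1)
    z <- rnorm(d) * sample(c(1, 1.5, 2.5), 1)
    expect_equal(gbjStatistic(z, diag(d)), bruteBerkJones(z),
                 tolerance = 1e-8)
  }
  expect_equal(gbjStatistic(rep(0, 10), diag(10)), 0)
})

test_that("GBJ statistic is invariant to ordering and sign flips", {
  set.seed(213)
  d <- 20
  sigma <- matrix(0.4, d, d); diag(sigma) <- 1
  z <- as.numeric(nullZSampler(sigma, 1, seed = 5)) + 1
  s0 <- gbjStatistic(z, sigma)
  perm <- sample(d)
  expect_equal(gbjStatistic(z[perm], sigma[perm, perm]), s0,
               tolerance = 1e-10)
  expect_equal(gbjStatistic(-z, sigma), s0, tolerance = 1e-10)
})

test_that("Monte-Carlo p-values honour the add-one floor and d=1 limit", {
  expect_error(gbjPvalue(1, diag(2), n_mc = 50, seed = 1), "refusing")
  expect_warning(gbjPvalue(0, diag(2), n_mc = 500, seed = 1), "poor")
  pv <- gbjPvalue(0, diag(3), n_mc = 2000, seed = 3)
  expect_gte(pv$p, 1 / 2001)
  expect_gt(pv$p, 0.9)              # zero statistic is null-typical
  ## d = 1: GBJ p matches the two-sided normal p within MC error
  for (z in c(1.8, 2.6)) {
    st <- gbjStatistic(z, diag(1))
    pv <- gbjPvalue(st, diag(1), n_mc = 20000, seed = 7)
    exact <- 2 * pnorm(-z)
    expect_lt(abs(pv$p - exact), 3 * sqrt(exact * (1 - exact) / 20000))
  }
})

test_that("GBJ beats Bonferroni min-p in the sparse-signal regime", {
  d <- 50
  sigma <- diag(d)
  null_stats <- gbjStatBatch(nullZSampler(sigma, 4000, seed = 21), sigma)
  q95_gbj <- quantile(null_stats, 0.95, type = 7)
  alpha_bonf <- 0.05 / d
  set.seed(22)
  reps <- 200
  win_gbj <- win_bonf <- 0
  for (r in seq_len(reps)) {
    z <- rnorm(d)
    z[1:3] <- z[1:3] + 3.5          # sparse alternative
    win_gbj <- win_gbj + (gbjStatistic(z, sigma) > q95_gbj)
    win_bonf <- win_bonf + (2 * pnorm(-max(abs(z))) < alpha_bonf)
  }
  expect_gte(win_gbj, win_bonf)
  expect_gt(win_gbj / reps, 0.5)
})

test_that("individual-level region test composes prune, scores and GBJ", {
  pool <- sharedPool()
  vids <- sprintf("snp%06d", seq_along(pool@maf))
  j <- 140
  reg1 <- region("1", pool@pos[j] - 1, pool@pos[j] + 1)   # single SNP
  st <- simulateStudy(pool, 400, 400, seed = 221)
  res <- testRegionIndividual(st, reg1, n_mc = 4000, seed = 23)
  expect_equal(res$n_snps_tested, 1)
  expect_true(res$p > 0 && res$p <= 1)
  ## planted effect at common variants detected in a wider region
  reg2 <- region("1", pool@pos[120], pool@pos[160])
  maf <- pmin(pool@maf, 1 - pool@maf)
  pick <- (120:160)[order(maf[120:160], decreasing = TRUE)[1:3]]
  ef <- effectSpec(reg2, vids[pick], 1.4)
  hits <- vapply(1:10, function(s) {
    st2 <- simulateStudy(pool, 800, 800, effects = list(ef),
                         seed = 230 + s)
    testRegionIndividual(st2, reg2, n_mc = 2000, seed = 24)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.5)
})

test_that("summary-statistics GBJ agrees with the individual-level test", {
  pool <- sharedPool()
  vids <- sprintf("snp%06d", seq_along(pool@maf))
  reg <- region("1", pool@pos[40], pool@pos[80])
  maf <- pmin(pool@maf, 1 - pool@maf)
  pick <- (40:80)[order(maf[40:80], decreasing = TRUE)[1:2]]
  ef <- effectSpec(reg, vids[pick], 1.5)
  st <- simulateStudy(pool, 900, 900, effects = list(ef), seed = 241)
  ## summary stats computed from the same genotypes
  si <- sampleInfo(st)
  ref <- simulateStudy(pool, 300, 300, seed = 243, study = "ref")
  ss <- emitSummaryStudy(pool, 900, 900, effects = list(ef), seed = 241)
  res_sum <- testRegionSummary(ss, reg, ref, n_mc = 4000, seed = 25)
  res_ind <- testRegionIndividual(st, reg, n_mc = 4000, seed = 26,
                                  r2_max = 1.1)  # keep all SNPs
  ## same planted signal: both reject; log p within a factor
  expect_lt(res_sum$p, 0.05)
  expect_lt(res_ind$p, 0.05)
  ## allele flips are corrected by sign inversion
  ss_fl <- ss
  flip <- seq(1, nrow(ss_fl), by = 2)
  tmp <- ss_fl$a1[flip]
  ss_fl$a1[flip] <- ss_fl$a2[flip]
  ss_fl$a2[flip] <- tmp
  ss_fl$beta[flip] <- -ss_fl$beta[flip]
  res_fl <- testRegionSummary(ss_fl, reg, ref, n_mc = 4000, seed = 25)
  expect_equal(res_fl$stat, res_sum$stat, tolerance = 1e-12)
  expect_equal(res_fl$p, res_sum$p)
  ## unmatched SNPs are dropped and counted
  ss_un <- ss
  in_reg <- which(ss_un$pos >= pool@pos[40] & ss_un$pos <= pool@pos[80])
  ss_un$a1[in_reg[2]] <- "T"; ss_un$a2[in_reg[2]] <- "C"
  res_un <- testRegionSummary(ss_un, reg, ref, n_mc = 1000, seed = 27)
  expect_gte(res_un$n_snps_dropped, 1)
})
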