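test_that("effect recovery from printed OR and CI round-trips", {
  bc <- betaFromOrCi(0.75, 0.58, 0.97)
  expect_equal(bc$beta, log(0.75))
  expect_equal(bc$se, (log(0.97) - log(0.58)) / (2 * 1.96))
  ## round trip through OR/CI and back
  or_ <- exp(bc$beta); l <- exp(bc$beta - 1.96 * bc$se)
  u <- exp(bc$beta + 1.96 * bc$se)
  bc2 <- betaFromOrCi(or_, l, u)
  expect_equal(bc2$beta, bc$beta, tolerance = 1e-12)
  expect_equal(bc2$se, bc$se, tolerance = 1e-12)
  ## symmetric null
  bc3 <- betaFromOrCi(1.0, 1 / 1.2, 1.2)
  expect_equal(bc3$beta, 0)
  expect_equal(bc3$p, 1)
  expect_error(betaFromOrCi(0.9, 0.95, 1.2), "l95 < or_")
})

test_that("published per-SNP rows reproduce their printed Wald p", {
  tab <- publishedAssoc()
  ## printed p reconstructed from printed OR/CI within the z tolerance
  ## induced by two-decimal rounding; near-null rows (OR ~ 1, narrow CI)
  ## carry the largest rounding error, so the blanket band is wider than
  ## the 0.05 used for the strong anchor rows in the acceptance tests
  for (i in seq_len(nrow(tab))) {
    bc <- betaFromOrCi(tab$or_[i], tab$l95[i], tab$u95[i])
    z_printed <- qnorm(tab$p[i] / 2, lower.tail = FALSE)
    expect_lt(abs(abs(bc$z) - z_printed), 0.15)
  }
})

test_that("effective sample size behaves like a balanced-design size", {
  expect_equal(effectiveN(1000, 1000), 2000)
  expect_equal(effectiveN(346, 962), 4 / (1 / 346 + 1 / 962))
  expect_equal(round(effectiveN(346, 962), 1), 1017.9)
  ## monotone in each argument
  expect_gt(effectiveN(400, 962), effectiveN(346, 962))
  expect_gt(effectiveN(346, 1100), effectiveN(346, 962))
  expect_error(effectiveN(0, 10))
})

test_that("weighted-Z meta matches the Stouffer closed form", {
  ## k identical studies: |z_meta| = sqrt(k) |z_single|
  p1 <- 0.04
  z1 <- qnorm(p1 / 2, lower.tail = FALSE)
  for (k in c(2, 4)) {
    m <- weightedZMeta(rep(p1, k), rep(1, k), rep(500, k), rep(500, k))
    expect_equal(m$z_meta, sqrt(k) * z1, tolerance = 1e-12)
  }
  ## opposite directions cancel exactly
  m0 <- weightedZMeta(c(0.01, 0.01), c(1, -1), c(300, 300), c(300, 300))
  expect_equal(m0$z_meta, 0)
  expect_equal(m0$p_meta, 1)
  ## invariant to study ordering
  p <- c(0.3, 0.01, 0.2); dd <- c(1, -1, 1)
  nc <- c(100, 400, 250); nn <- c(150, 350, 250)
  m1 <- weightedZMeta(p, dd, nc, nn)
  o <- c(3, 1, 2)
  m2 <- weightedZMeta(p[o], dd[o], nc[o], nn[o])
  expect_equal(m1$z_meta, m2$z_meta)
  ## p = 0 clipped with warning
  expect_warning(weightedZMeta(c(0, 0.5), c(1, 1), c(10, 10),
                               c(10, 10)), "clipped")
})

test_that("sex-difference test is symmetric and matches its formula", {
  f <- data.frame(vid = "v", beta = 0.3, se = 0.1)
  m <- data.frame(vid = "v", beta = 0.1, se = 0.15)
  r <- sexDifference(f, m)
  expect_equal(r$beta_diff, 0.2)
  expect_equal(r$se_diff, sqrt(0.1^2 + 0.15^2))
  expect_gte(r$se_diff, max(f$se, m$se))
  expect_equal(r$p_diff, 2 * pnorm(-0.2 / sqrt(0.0325)))
  ## equal effects: p = 1; swapping sexes flips the sign only
  expect_equal(sexDifference(f, f)$p_diff, 1)
  r2 <- sexDifference(m, f)
  expect_equal(r2$beta_diff, -r$beta_diff)
  expect_equal(r2$p_diff, r$p_diff)
  expect_error(sexDifference(f, data.frame(vid = "w", beta = 0, se = 1)),
               "different variants")
})

test_that("Bonferroni ledger matches the published thresholds", {
  expect_equal(round(bonferroniThreshold(0.05, 61), 3), 0.001)
  expect_equal(signif(bonferroniThreshold(0.05, 15148), 3), 3.30e-6)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
})

test_that("per-SNP logistic fit is calibrated and guards degeneracy", {
  pool <- sharedPool()
  vids <- sprintf("snp%06d", seq_along(pool@maf))
  target <- vids[300]
  reg <- region("1", pool@pos[300] - 1, pool@pos[300] + 1)
  ef <- effectSpec(reg, target, 1.5)
  covered <- vapply(1:60, function(s) {
    st <- simulateStudy(pool, 300, 300, effects = list(ef),
                        seed = 900 + s)
    row <- snpLogistic(st, target)
    row$l95 <= 1.5 && 1.5 <= row$u95
  }, logical(1))
  expect_gt(mean(covered), 0.87)   # nominal 0.95, binomial noise at 60
  ## null p-values uniform-ish
  pvals <- vapply(1:40, function(s) {
    st <- simulateStudy(pool, 200, 200, seed = 1300 + s)
    snpLogistic(st, vids[17])$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  ## constant SNP is an estimation error
  st <- simulateStudy(pool, 50, 50, seed = 1401)
  G <- dosage(st); G[, 1] <- 1L
  st2 <- StudyGenotypes(G, variantInfo(st),
                        sampleInfo(st)[, c("sid", "phenotype", "sex",
                                           "age")])
  expect_error(snpLogistic(st2, variantInfo(st2)$vid[1]), "constant")
})

test_that("published meta p-values are reproduced from printed inputs", {
  tab <- publishedAssoc()
  cnt <- publishedCounts()
  metaFor <- function(vid, sex) {
    rows <- tab[tab$vid == vid & tab$sex == sex, ]
    rows <- merge(rows, cnt, by = c("study", "sex"))
    dir <- ifelse(rows$or_ >= 1, 1, -1)
    weightedZMeta(rows$p, dir, rows$n_case, rows$n_ctrl)
  }
  ## male rs35042965: printed meta P = 1.54e-6
  m <- metaFor("rs35042965", "male")
  z_paper <- qnorm(1.54e-6 / 2, lower.tail = FALSE)
  expect_lt(abs(abs(m$z_meta) - z_paper) / z_paper, 0.05)
  expect_equal(m$directions, "----")
  ## female rs2346609: printed meta P = 3.21e-7
  f <- metaFor("rs2346609", "female")
  z_paper_f <- qnorm(3.21e-7 / 2, lower.tail = FALSE)
  expect_lt(abs(abs(f$z_meta) - z_paper_f) / z_paper_f, 0.05)
  ## effective-N weighting fits the printed values better than total-N
  mt <- {
    rows <- tab[tab$vid == "rs35042965" & tab$sex == "male", ]
    rows <- merge(rows, cnt, by = c("study", "sex"))
    weightedZMeta(rows$p, ifelse(rows$or_ >= 1, 1, -1), rows$n_case,
                  rows$n_ctrl, weighting = "total")
  }
  expect_lt(abs(abs(m$z_meta) - z_paper),
            abs(abs(mt$z_meta) - z_paper))
})

test_that("published sex-difference p-values are reproduced", {
  tab <- publishedAssoc()
  printed <- data.frame(
    vid = c("rs2346609", "rs2346609", "rs35042965"),
    study = c("UCSF_Mayo", "GICC", "GICC"),
    p_diff = c(0.0131, 0.0066, 0.0702))
  for (i in seq_len(nrow(printed))) {
    rw <- function(sx) {
      r <- tab[tab$vid == printed$vid[i] & tab$study == printed$study[i] &
                 tab$sex == sx, ]
      bc <- betaFromOrCi(r$or_, r$l95, r$u95)
      data.frame(vid = r$vid, beta = bc$beta, se = bc$se)
    }
    r <- sexDifference(rw("female"), rw("male"))
    z_printed <- qnorm(printed$p_diff[i] / 2, lower.tail = FALSE)
    expect_lt(abs(abs(r$z_diff) - z_printed), 0.1)
  }
})

test_that("summary tables are joined allele-aware before meta-analysis", {
  mk <- function(flip = FALSE, beta = 0.2) {
    df <- data.frame(chrom = "1", pos = c(100, 200),
                     vid = c("a", "b"), a1 = c("A", "C"),
                     a2 = c("G", "T"), beta = beta, se = 0.1,
                     p = 2 * pnorm(-abs(beta) / 0.1),
                     n_case = 500, n_ctrl = 500)
    if (flip) {
      df$a1 <- c("G", "T"); df$a2 <- c("A", "C"); df$beta <- -df$beta
    }
    df
  }
  m1 <- metaSummaryStats(list(s1 = mk(), s2 = mk()))
  m2 <- metaSummaryStats(list(s1 = mk(), s2 = mk(flip = TRUE)))
  expect_equal(m1$z_meta, m2$z_meta, tolerance = 1e-12)
  expect_equal(m1$directions, c("++", "++"))
})
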