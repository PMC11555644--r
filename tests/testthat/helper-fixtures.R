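## Shared fixtures, built once per test run and cached in this
## environment.  All fixtures are generated in code from fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

## tiny deterministic study: 6 samples x 4 SNPs with a missing call
tinyStudy <- function() {
  StudyGenotypes(
    dosage = matrix(c(0L, 1L, 2L, 0L, 1L, 2L,
                      2L, 2L, 1L, 0L, 0L, 1L,
                      NA, 1L, 1L, 1L, 2L, 0L,
                      0L, 0L, 0L, 1L, 1L, 2L), nrow = 6),
    variants = data.frame(chrom = "1", pos = c(100L, 220L, 340L, 460L),
                          vid = paste0("v", 1:4), a1 = "A", a2 = "G"),
    samples = data.frame(sid = paste0("s", 1:6),
                         phenotype = rep(c("case", "control"), 3),
                         sex = rep(c("male", "female"), each = 3),
                         age = c(50, 61, 55, 48, 66, 59)))
}

## random small study for property tests
randomStudy <- function(n = 20, m = 30, seed = 1, miss = 0.05) {
  set.seed(seed)
  dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  dos[matrix(runif(n * m) < miss, n, m)] <- NA_integer_
  storage.mode(dos) <- "integer"
  StudyGenotypes(
    dosage = dos,
    variants = data.frame(chrom = "1", pos = seq_len(m) * 50L,
                          vid = sprintf("v%03d", seq_len(m)),
                          a1 = "A", a2 = "C"),
    samples = data.frame(sid = sprintf("s%03d", seq_len(n)),
                         phenotype = sample(c("case", "control"), n,
                                            replace = TRUE,
                                            prob = c(0.5, 0.5)),
                         sex = sample(c("male", "female"), n,
                                      replace = TRUE),
                         age = round(runif(n, 40, 75))))
}

## mid-size LD pool shared by several files
sharedPool <- function() {
  fixture("shared_pool", function()
    buildHaplotypePool(n_hap = 1000, n_snp = 400, block_len = 20,
                       seed = 4242))
}

## published per-study association rows and stratum counts
publishedAssoc <- function() {
  read.table(system.file("extdata", "published_snp_associations.tsv",
                         package = "regionwas"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

publishedCounts <- function() {
  read.table(system.file("extdata", "published_stratum_counts.tsv",
                         package = "regionwas"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

## brute-force standard Berk-Jones statistic (independence), the oracle
## for the GBJ independence reduction
bruteBerkJones <- function(z) {
  d <- length(z)
  a <- sort(abs(z), decreasing = TRUE)
  best <- 0
  for (k in seq_len(d)) {
    if (a[k] <= 1) next
    p <- 2 * pnorm(-a[k])
    if (k / d <= p) next
    best <- max(best, log(dbinom(k, d, k / d)) - log(dbinom(k, d, p)))
  }
  best
}

## brute-force iterative LD pruning on a full r^2 matrix (no windows):
## repeatedly drop one member of the worst pair until none exceeds r2max
brutePrune <- function(G, r2max) {
  m <- ncol(G)
  af <- colMeans(G) / 2
  maf <- pmin(af, 1 - af)
  keep <- rep(TRUE, m)
  repeat {
    w <- which(keep)
    if (length(w) < 2) break
    cc <- suppressWarnings(cor(G[, w, drop = FALSE]))
    cc[is.na(cc)] <- 0
    r2 <- cc^2; diag(r2) <- 0
    mx <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    if (r2[mx[1], mx[2]] <= r2max) break
    a <- w[mx[1]]; b <- w[mx[2]]
    drop <- if (maf[a] < maf[b]) a
            else if (maf[b] < maf[a]) b else max(a, b)
    keep[drop] <- FALSE
  }
  which(keep)
}

## Cochran-Armitage trend test z from the 2x3 genotype table
trendTestZ <- function(g, y) {
  x <- 0:2
  n <- length(y)
  ni <- vapply(x, function(v) sum(g == v), numeric(1))
  ri <- vapply(x, function(v) sum(g == v & y == 1), numeric(1))
  r <- sum(y)
  num <- n * sum(x * ri) - r * sum(x * ni)
  den <- r * (n - r) * (n * sum(x^2 * ni) - sum(x * ni)^2) / n
  num / sqrt(den)
}
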