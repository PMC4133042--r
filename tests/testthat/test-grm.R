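test_that("GRM matches a hand computation on a toy panel", {
  ## 3 SNPs x 2 samples
  d <- matrix(c(0L, 2L,
                1L, 1L,
                2L, 0L), nrow = 3, byrow = TRUE)
  g <- makeToyGenotypes(d)
  grm <- computeGRM(g)
  p <- rowMeans(d) / 2
  w <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  expect_equal(grmValues(grm), unname(crossprod(w) / 3), tolerance = 1e-12)
  expect_true(all(grmNsnp(grm) == 3L))
})

test_that("duplicate individuals have off-diagonal equal to the diagonal", {
  set.seed(10)
  x <- rbinom(60, 2, 0.3)
  d <- cbind(x, x, rbinom(60, 2, 0.3), rbinom(60, 2, 0.4))
  p <- rowMeans(d) / 2
  g <- makeToyGenotypes(d[p > 0 & p < 1, ])
  grm <- computeGRM(g)
  expect_equal(grmValues(grm)[1, 2], grmValues(grm)[1, 1], tolerance = 1e-12)
})

test_that("GRM diagonal averages 1 under HWE and symmetry holds exactly", {
  cfg <- simConfig(nSubjects = 200, nSnps = 2000, nCausal = 10, seed = 14)
  grm <- computeGRM(simulateGenotypes(cfg))
  expect_gt(mean(diag(grmValues(grm))), 0.95)
  expect_lt(mean(diag(grmValues(grm))), 1.05)
  expect_lt(max(abs(grmValues(grm) - t(grmValues(grm)))), 1e-12)
})

test_that("GRM values follow a sample permutation", {
  cfg <- simConfig(nSubjects = 40, nSnps = 300, nCausal = 10, seed = 15)
  g <- simulateGenotypes(cfg)
  perm <- sample(seq_len(40))
  a1 <- grmValues(computeGRM(g))
  a2 <- grmValues(computeGRM(g[, perm]))
  expect_equal(a2, a1[perm, perm], tolerance = 1e-12)
})

test_that("monomorphic SNPs are rejected by computeGRM", {
  d <- rbind(rep(0L, 10), rbinom(10, 2, 0.4))
  expect_error(computeGRM(makeToyGenotypes(d)), "MAF")
})

test_that("missing dosages impute to 2p and shrink per-pair SNP counts", {
  set.seed(30)
  d <- matrix(rbinom(200 * 20, 2, 0.3), 200, 20)
  d[1:50, 1] <- NA
  grm <- computeGRM(makeToyGenotypes(d))
  expect_identical(grmNsnp(grm)[1, 2], 150L)
  expect_identical(grmNsnp(grm)[2, 3], 200L)
  expect_true(all(is.finite(grmValues(grm))))
})

test_that("relatedness pruning is greedy, deterministic and sufficient", {
  base <- diag(6)
  expect_true(all(pruneRelated(grmFromMatrix(base))$keep))

  one <- base; one[1, 2] <- one[2, 1] <- 0.10
  pr <- pruneRelated(grmFromMatrix(one))
  expect_identical(sum(!pr$keep), 1L)
  expect_identical(pr$removed, 1L)       # tie broken toward the lower index

  star <- diag(6)
  star[1, 2:6] <- star[2:6, 1] <- 0.2
  prS <- pruneRelated(grmFromMatrix(star))
  expect_identical(prS$removed, 1L)      # only the hub goes
  expect_identical(sum(prS$keep), 5L)

  set.seed(77)
  a <- matrix(runif(100, -0.02, 0.09), 10, 10)
  a <- (a + t(a)) / 2; diag(a) <- 1
  prR <- pruneRelated(grmFromMatrix(a))
  sub <- a[prR$keep, prR$keep]
  expect_lte(max(sub[upper.tri(sub)]), 0.05)
})

test_that("GRM principal components separate simulated populations", {
  set.seed(55)
  n <- 80; m <- 500
  p1 <- runif(m, 0.1, 0.5)
  shift <- ifelse(runif(m) < 0.3, 0.3, 0)    # differentiated SNPs
  p2 <- pmin(p1 + shift, 0.95)
  d <- cbind(matrix(rbinom(m * n / 2, 2, p1), m, n / 2),
             matrix(rbinom(m * n / 2, 2, p2), m, n / 2))
  poly <- rowMeans(d) / 2
  d <- d[poly > 0.01 & poly < 0.99, ]
  pcs <- grmPCA(computeGRM(makeToyGenotypes(d)), k = 5)
  popLabel <- rep(c(0, 1), each = n / 2)
  expect_gt(abs(cor(pcs[, 1], popLabel)), 0.9)
  expect_equal(crossprod(pcs), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("degenerate spectra still yield orthonormal scores and k checks", {
  grm <- grmFromMatrix(diag(12))
  pcs <- grmPCA(grm, k = 4)
  expect_equal(crossprod(pcs), diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(grmPCA(grm, k = 12), "smaller than")
})

test_that("GCTA text round-trip is lossless and checks its id file", {
  cfg <- simConfig(nSubjects = 15, nSnps = 100, nCausal = 5, seed = 16)
  grm <- computeGRM(snpQC(simulateGenotypes(cfg))$genotypes)
  pre <- file.path(tempdir(), "g1")
  writeGRM(grm, pre)
  back <- readGRM(pre)
  expect_equal(grmValues(back), grmValues(grm), tolerance = 1e-6)
  expect_identical(grmNsnp(back), grmNsnp(grm))
  expect_equal(sampleIds(back)$IID, sampleIds(grm)$IID)

  ## 2x2 hand-written file
  pre2 <- file.path(tempdir(), "g2")
  writeLines(c("1\t1\t10\t1.01", "2\t1\t10\t0.05", "2\t2\t10\t0.99"),
             paste0(pre2, ".grm.txt"))
  writeLines(c("F1\tI1", "F2\tI2"), paste0(pre2, ".grm.id"))
  h <- readGRM(pre2)
  expect_equal(grmValues(h), matrix(c(1.01, 0.05, 0.05, 0.99), 2, 2))

  writeLines("F1\tI1", paste0(pre2, ".grm.id"))
  expect_error(readGRM(pre2), "id file")
})
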