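test_that("genotype sampling follows the generating allele frequencies", {
  cfg <- simConfig(nSubjects = 10000, nSnps = 5, mafRange = c(0.5, 0.5),
                   nCausal = 1, seed = 42)
  g <- simulateGenotypes(cfg)
  ## p = 0.5 for every SNP: mean dosage 1.0 within 3 SE
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_true(all(abs(rowMeans(dosages(g)) - 1) < 3 * se))
  expect_false(anyNA(dosages(g)))   # missingRate = 0 injects nothing

  cfg2 <- simConfig(nSubjects = 2000, nSnps = 1, mafRange = c(0.2, 0.2),
                    nCausal = 1, seed = 7)
  g2 <- simulateGenotypes(cfg2)
  se2 <- sqrt(0.2 * 0.8 / 4000)
  expect_lt(abs(alleleFreq(g2) - 0.2), 3 * se2)
})

test_that("allele frequencies converge to the generating p across a panel", {
  cfg <- simConfig(nSubjects = 2000, nSnps = 200, nCausal = 10, seed = 5)
  g <- simulateGenotypes(cfg)
  p <- snpMeta(g)$p
  se <- sqrt(p * (1 - p) / (2 * 2000))
  expect_true(all(abs(alleleFreq(g) - p) < 3.5 * se))
})

test_that("missingness is injected at the configured rate and never at zero", {
  cfg <- simConfig(nSubjects = 500, nSnps = 200, nCausal = 10,
                   missingRate = 0.1, seed = 2)
  g <- simulateGenotypes(cfg)
  miss <- mean(is.na(dosages(g)))
  expect_lt(abs(miss - 0.1), 3 * sqrt(0.1 * 0.9 / (500 * 200)))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(mafRange = c(0, 0.5)), "mafRange")
  expect_error(simConfig(mafRange = c(0.1, 0.6)), "mafRange")
  expect_error(simConfig(targetH2 = 1.2), "targetH2")
  expect_error(simConfig(nSnps = 10, nCausal = 20), "nCausal")
  bad <- matrix(0.9, 3, 3); diag(bad) <- 1; bad[1, 2] <- -0.9
  expect_error(simConfig(roiCount = 3, roiPhenoCorr = bad), "symmetric")
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- simConfig(nSubjects = 50, nSnps = 100, nCausal = 10, seed = 99)
  expect_identical(dosages(simulateGenotypes(cfg)),
                   dosages(simulateGenotypes(cfg)))
  expect_identical(simulateMultiRoiPhenotypes(simulateGenotypes(cfg), cfg),
                   simulateMultiRoiPhenotypes(simulateGenotypes(cfg), cfg))
  g1 <- simulateSubjectGraphs(cfg, 5)
  g2 <- simulateSubjectGraphs(cfg, 5)
  expect_identical(g1, g2)
  expect_identical(simulateBoldSession(cfg, g1[[1]], seed = 11)@signal,
                   simulateBoldSession(cfg, g1[[1]], seed = 11)@signal)
})

test_that("phenotypes hit the stated variance decomposition", {
  cfg <- simConfig(nSubjects = 2000, nSnps = 1000, nCausal = 100,
                   targetH2 = 0.5, siteSd = 0, sexEffect = 0, seed = 21)
  g <- simulateGenotypes(cfg)
  ph <- simulateMultiRoiPhenotypes(g, cfg, seed = NULL)
  y <- as.matrix(ph[, faceRoiNames()])
  ## realized phenotypic variance within 10% of VG + VE = 1
  expect_true(all(abs(apply(y, 2, var) - 1) < 0.1))
  ## genetic values carry the target share of variance
  gv <- attr(ph, "geneticValues")
  expect_true(all(abs(apply(gv, 2, var) - 0.5) < 0.1))
})

test_that("a zero-heritability phenotype is independent of genotype", {
  cfg <- simConfig(nSubjects = 800, nSnps = 500, nCausal = 50,
                   targetH2 = 0, siteSd = 0, sexEffect = 0, seed = 31)
  g <- simulateGenotypes(cfg)
  ph <- simulateMultiRoiPhenotypes(g, cfg, seed = NULL)
  expect_true(all(attr(ph, "geneticValues") == 0))
  fit <- remlUnivariate(ph[[faceRoiNames()[1]]], NULL, computeGRM(g))
  expect_lt(fit@ratio, 0.25)
})

test_that("non-PSD environmental correlation fails with a diagnostic", {
  cfg <- simConfig(nSubjects = 20, nSnps = 50, nCausal = 5, seed = 1)
  ## corrupt the slot directly to bypass constructor validity
  bad <- cfg
  cc <- matrix(0.99, 3, 3); cc[1, 3] <- cc[3, 1] <- -0.99; diag(cc) <- 1
  bad@roiPhenoCorr <- cc
  bad@roiCount <- 3L
  bad@roiNames <- c("A", "B", "C")
  g <- simulateGenotypes(cfg)
  expect_error(simulateMultiRoiPhenotypes(g, bad), "positive semi-definite")
})

test_that("subject graphs match the connection probabilities in expectation", {
  p <- diag(25)
  p[2, 5] <- p[5, 2] <- 0.5
  cfg <- simConfig(nSubjects = 400, nSnps = 10, nCausal = 1,
                   pairConnectionProb = p, seed = 13)
  graphs <- simulateSubjectGraphs(cfg)
  obs <- mean(vapply(graphs, function(a) a[2, 5], logical(1)))
  expect_lt(abs(obs - 0.5), 3 * sqrt(0.25 / 400))
  ## pairs with probability 0 never connect
  expect_true(all(vapply(graphs, function(a) a[1, 3] == 0, logical(1))))
})

test_that("BOLD sessions honour the design and the coupling ground truth", {
  cfg <- simConfig(nSubjects = 10, nSnps = 10, nCausal = 1, seed = 3)
  empty <- matrix(FALSE, 25, 25)
  ts <- simulateBoldSession(cfg, empty, seed = 8)
  expect_s4_class(ts, "RoiTimeSeries")
  expect_identical(nrow(ts@signal), 160L)
  g0 <- buildConnectivityGraph(ts)
  expect_true(all(degree(g0) == 0L))

  full <- !diag(25); diag(full) <- FALSE
  cfgHi <- simConfig(nSubjects = 10, nSnps = 10, nCausal = 1,
                     coupling = 0.7, seed = 3)
  tsF <- simulateBoldSession(cfgHi, full, seed = 9)
  expect_true(all(degree(buildConnectivityGraph(tsF)) == 24L))

  ## a 1-probability pair is always detected; 0.5 pair observed near 0.5
  p <- diag(25); p[1, 2] <- p[2, 1] <- 0.5
  cfgP <- simConfig(nSubjects = 400, nSnps = 10, nCausal = 1,
                    pairConnectionProb = p, seed = 17)
  co <- simulateBoldCohort(cfgP)
  prop <- connectionProportions(lapply(co$sessions, buildConnectivityGraph))
  expect_lt(abs(prop[1, 2] - 0.5), 3 * sqrt(0.25 / 400) + 0.02)
})

test_that("a malformed design is an invalid-config error", {
  cfg <- simConfig(nSubjects = 5, nSnps = 10, nCausal = 1, seed = 1)
  short <- cfg
  short@blockDesign <- rep("control", 80)
  expect_error(simulateBoldSession(short, matrix(FALSE, 25, 25)),
               "160 volumes")
  expect_error(simConfig(blockDesign = rep("control", 100)), "160")
})

test_that("BOLD sessions round-trip through the TSV exchange format", {
  cfg <- simConfig(nSubjects = 2, nSnps = 10, nCausal = 1, seed = 23)
  ts <- simulateBoldSession(cfg, matrix(FALSE, 25, 25), seed = 5)
  pre <- file.path(tempdir(), "sess1")
  writeBoldSession(ts, pre)
  back <- readBoldSession(pre)
  expect_equal(unname(back@signal), unname(ts@signal), tolerance = 1e-6)
  expect_identical(back@design, ts@design)
})
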