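test_that("expected false-positive counts follow n * alpha", {
  expect_identical(expectedFalsePositives(25, 0.05), 1.25)
  expect_identical(expectedFalsePositives(50, 0.05), 2.5)
  expect_identical(expectedFalsePositives(1000, 0), 0)
})

test_that("a count of zero always gets Monte-Carlo p = 1", {
  corr <- matrix(0.6, 25, 25); diag(corr) <- 1
  d <- mcCountPvalue(corr, observedCount = 0, nRealizations = 500, seed = 3)
  expect_identical(d@pValue, 1)
  expect_error(mcCountPvalue(corr, 26), "observedCount")
  expect_error(mcCountPvalue(corr, -1), "observedCount")
})

test_that("the independence limit reproduces the binomial count law", {
  d <- mcCountPvalue(diag(25), observedCount = 9,
                     nRealizations = 50000, seed = 5)
  counts <- 0:25
  pBinom <- dbinom(counts, 25, 0.05)
  ## chi-square goodness of fit on pooled bins with expected >= 5
  expected <- 50000 * pBinom
  bins <- pmin(counts, 4)        # pool counts >= 4
  obs <- tapply(as.numeric(d@histogram), bins, sum)
  exp <- tapply(expected, bins, sum)
  stat <- sum((obs - exp)^2 / exp)
  expect_lt(stat, qchisq(0.99, df = length(obs) - 1))
  ## the MC tail at 9 matches the exact binomial tail
  tailMC <- (1 + sum(d@histogram[as.character(9:25)])) / (1 + 50000)
  tailExact <- pbinom(8, 25, 0.05, lower.tail = FALSE)
  expect_lt(abs(tailMC - tailExact), 3 * sqrt(tailExact / 50000) + 1e-4)
  expect_equal(d@pValue, tailMC)
})

test_that("perfect dependence concentrates the count on the extremes", {
  ones <- matrix(1, 25, 25)
  d <- mcCountPvalue(ones, 5, nRealizations = 5000, seed = 6)
  mass <- sum(d@histogram[c("0", "25")]) / 5000
  expect_gt(mass, 0.99)
  ## an indefinite matrix triggers the nearest-PSD repair
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_warning(mcCountPvalue(bad, 1, nRealizations = 200, seed = 6), "PSD")
})

test_that("the Monte-Carlo p is monotone in the observed count", {
  corr <- matrix(0.4, 25, 25); diag(corr) <- 1
  ps <- vapply(0:25, function(k)
    mcCountPvalue(corr, k, nRealizations = 2000, seed = 7)@pValue, numeric(1))
  expect_true(all(diff(ps) <= 0))
  ## fixed seed, fixed draw: bit-reproducible
  expect_identical(mcCountPvalue(corr, 9, nRealizations = 2000, seed = 7),
                   mcCountPvalue(corr, 9, nRealizations = 2000, seed = 7))
})

test_that("both null mechanisms are available and calibrated", {
  dN <- mcCountPvalue(diag(10), 2, nRealizations = 20000, seed = 8,
                      mechanism = "normal")
  dM <- mcCountPvalue(diag(10), 2, nRealizations = 20000, seed = 8,
                      mechanism = "mixture")
  ## each coordinate is significant with probability alpha under both
  for (d in list(dN, dM)) {
    meanCount <- sum(as.numeric(names(d@histogram)) * d@histogram) / 20000
    expect_lt(abs(meanCount - 10 * 0.05), 3 * sqrt(10 * 0.05 * 0.95 / 20000))
  }
})

test_that("trend fits agree with closed-form least squares", {
  x <- c(1, 2, 3, 4)
  y <- c(2.1, 3.9, 6.2, 7.8)
  f <- fitLinearTrend(x, y)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(unname(f@coefficients["x"]), slope, tolerance = 1e-12)
  expect_equal(f@df1, 1); expect_equal(f@df2, 2)

  exact <- suppressWarnings(fitLinearTrend(x, 2 * x))  # perfect fit
  expect_equal(exact@r2, 1, tolerance = 1e-12)

  para <- suppressWarnings(fitQuadraticTrend(x, 3 + x - 0.5 * x^2))
  expect_equal(para@r2, 1, tolerance = 1e-10)
  expect_lt(para@coefficients[["I(x^2)"]], 0)

  f25 <- fitQuadraticTrend(rnorm(25), rnorm(25))
  expect_equal(f25@df2, 22)           # n = 25 ROIs -> F(2, 22)
})

test_that("null trend p-values are uniform", {
  set.seed(9)
  ps <- vapply(seq_len(1000), function(i)
    fitLinearTrend(rnorm(25), rnorm(25))@pValue, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("inverted-U structure is detected on synthetic degree data", {
  set.seed(10)
  mean_d <- runif(25, 5, 15)
  sd_d <- 5 - 0.1 * (mean_d - 10)^2 + rnorm(25, 0, 0.2)
  f <- fitQuadraticTrend(mean_d, sd_d)
  expect_lt(f@coefficients[["I(x^2)"]], 0)
  expect_gt(f@r2, 0.5)
})

test_that("subnetwork classification recovers a constructed 4 + 4 split", {
  ## 4 Optional ROIs: highest degree SD at intermediate means;
  ## 4 Obligatory ROIs: highest means at the lowest SDs; 17 background.
  rois <- faceRoiNames()
  stats <- data.frame(roi = rois,
                      mean = rep(9, 25), sd = rep(4.0, 25))
  opt <- c("MVLFC_R", "MDLFC_L", "PMC_L", "AntSTS_R")
  obl <- c("PostSTS_R", "FFA_R", "LOC_L", "LOC_R")
  stats$mean[stats$roi %in% opt] <- c(10.2, 10.7, 10.5, 10.4)
  stats$sd[stats$roi %in% opt] <- c(4.9, 4.9, 5.1, 5.2)
  stats$mean[stats$roi %in% obl] <- c(14.0, 12.2, 12.3, 12.2)
  stats$sd[stats$roi %in% obl] <- c(3.4, 3.5, 3.3, 3.2)
  stats$mean[!stats$roi %in% c(opt, obl)] <-
    seq(5.5, 11.4, length.out = 17)
  stats$sd[!stats$roi %in% c(opt, obl)] <-
    seq(3.9, 4.8, length.out = 17)
  lab <- classifySubnetworks(stats)
  expect_setequal(names(lab@labels)[lab@labels == "Optional"], opt)
  expect_setequal(names(lab@labels)[lab@labels == "Obligatory"], obl)

  ## degenerate and edge cases
  expect_warning(l0 <- classifySubnetworks(
    data.frame(roi = rois, mean = 1, sd = 1)), "degenerate")
  expect_true(all(l0@labels == "Neither"))
  lz <- classifySubnetworks(stats, kOptional = 0, kObligatory = 0)
  expect_true(all(lz@labels == "Neither"))
  expect_error(classifySubnetworks(stats, kOptional = 20), "at most")
})

test_that("split-half reproducibility behaves at its limits", {
  m <- rnorm(25)
  expect_equal(splitHalfR2(m, m), 1, tolerance = 1e-12)
  set.seed(11)
  expect_lt(splitHalfR2(rnorm(25), rnorm(25)), 0.4)
  ## a cohort with stable ROI effects reproduces across halves
  cfg <- simConfig(nSubjects = 800, nSnps = 50, nCausal = 5,
                   targetH2 = 0.3, siteSd = 0, seed = 12)
  g <- simulateGenotypes(cfg)
  ph <- simulateMultiRoiPhenotypes(g, cfg, seed = NULL)
  ## add distinct per-ROI offsets (the stable regional response profile)
  offsets <- seq(-2, 2, length.out = 25)
  ph[, faceRoiNames()] <- sweep(as.matrix(ph[, faceRoiNames()]), 2, offsets, `+`)
  sh <- randomSplitHalfR2(ph, seed = 13)
  expect_gt(sh$r2, 0.9)
  expect_identical(sh$nA + sh$nB, 800L)
})
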