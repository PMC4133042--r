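toySession <- function(seed = 1, wmLeak = 0, csfLeak = 0, coupling = 0.5,
                       graph = matrix(FALSE, 25, 25)) {
  cfg <- simConfig(nSubjects = 2, nSnps = 10, nCausal = 1,
                   wmLeak = wmLeak, csfLeak = csfLeak, coupling = coupling,
                   seed = seed)
  simulateBoldSession(cfg, graph, seed = seed)
}

test_that("nuisance regression removes injected leakage and nothing else", {
  clean <- toySession(seed = 5)
  out <- regressNuisance(clean)
  rois <- roiChannels(clean)
  rs <- vapply(rois, function(r) cor(out@signal[, r], clean@signal[, r]), 1)
  ## zero leakage: output ~ input up to the ~2/159 variance share that OLS
  ## on two independent noise regressors absorbs at 160 volumes
  expect_gt(median(rs), 0.99)
  expect_true(all(rs > 0.97))

  leaky <- toySession(seed = 6, wmLeak = 0.8, csfLeak = 0.5)
  cleaned <- regressNuisance(leaky)
  ## residual association with the nuisance channels is gone
  for (r in rois[1:5]) {
    f <- summary(lm(cleaned@signal[, r] ~ leaky@signal[, "WM"] +
                      leaky@signal[, "CSF"]))
    expect_lt(abs(coef(f)["leaky@signal[, \"WM\"]", "Estimate"]),
              2 * coef(f)["leaky@signal[, \"WM\"]", "Std. Error"] + 1e-8)
  }
  ## the injected coefficient is recovered by the regression it inverts
  fit <- lm(leaky@signal[, rois[1]] ~ leaky@signal[, "WM"] +
              leaky@signal[, "CSF"])
  expect_lt(abs(coef(fit)[2] - 0.8), 2 * summary(fit)$coefficients[2, 2])

  ## an ROI that copies WM exactly is annihilated
  copycat <- clean
  copycat@signal[, rois[1]] <- copycat@signal[, "WM"]
  res <- regressNuisance(copycat)
  expect_lt(var(res@signal[, rois[1]]), 1e-12)
})

test_that("condition extraction honours the design arithmetic", {
  ts <- toySession(seed = 7)
  amb <- extractConditionSeries(ts, "ambiguous")
  ang <- extractConditionSeries(ts, "angry")
  ctl <- extractConditionSeries(ts, "control")
  expect_identical(nrow(amb), 40L)    # 5 blocks x 8 volumes
  expect_identical(nrow(ang), 40L)
  expect_identical(nrow(ctl), 72L)    # 9 blocks x 8 volumes
  ## per-block means vanish
  blockMeans <- colMeans(amb[1:8, , drop = FALSE])
  expect_lt(max(abs(blockMeans)), 1e-12)
  ## constant signal extracts to zero
  flat <- ts
  flat@signal[] <- 100
  expect_lt(max(abs(extractConditionSeries(flat, "ambiguous"))), 1e-12)
  expect_error(extractConditionSeries(ts, "rest"), "unknown condition")
  ## a shift that runs off the end errors instead of truncating
  late <- ts
  late@design <- c(rep("control", 152), rep("ambiguous", 8))
  expect_error(extractConditionSeries(late, "ambiguous"), "runs off")
})

test_that("correlation matrices behave at the trivial limits", {
  ts <- toySession(seed = 8)
  face <- extractConditionSeries(ts, "ambiguous")
  ctl <- extractConditionSeries(ts, "control")
  r <- conditionCorrelationMatrix(face, ctl)
  expect_identical(dim(r), c(25L, 25L))
  expect_equal(diag(r), rep(1, 25), ignore_attr = TRUE)
  ## duplicated and sign-flipped channels
  face2 <- cbind(face, dup = face[, 1], flip = -face[, 1])
  ctl2 <- cbind(ctl, dup = ctl[, 1], flip = -ctl[, 1])
  r2 <- conditionCorrelationMatrix(face2, ctl2)
  expect_equal(r2[1, "dup"], 1, tolerance = 1e-12)
  expect_equal(r2[1, "flip"], -1, tolerance = 1e-12)
  ## independent noise at 112 points rarely crosses the 0.3 threshold
  off <- r[upper.tri(r)]
  expect_gte(mean(abs(off) < 0.3), 0.95)
})

test_that("degree equals the brute-force count with a strict threshold", {
  set.seed(9)
  ## toy 5-node matrix
  r5 <- matrix(runif(25, -1, 1), 5, 5)
  r5 <- (r5 + t(r5)) / 2; diag(r5) <- 1
  g5 <- thresholdAndDegree(r5)
  expect_identical(degree(g5), degreeBruteForce(r5))
  ## exact-threshold pairs never edge
  rEdge <- diag(2); rEdge[1, 2] <- rEdge[2, 1] <- 0.3
  expect_true(all(degree(thresholdAndDegree(rEdge)) == 0L))
  expect_true(all(degree(thresholdAndDegree(diag(25))) == 0L))
  ## full 25-node instances, plus the handshake lemma
  for (s in 1:10) {
    z <- matrix(rnorm(112 * 25), 112, 25)
    r <- cor(z)
    g <- thresholdAndDegree(r)
    expect_identical(degree(g), degreeBruteForce(r))
    expect_identical(sum(degree(g)) %% 2L, 0L)
  }
})

test_that("percent signal change is a calibrated linear contrast", {
  ts <- toySession(seed = 10)
  ## built-in truth: the contrast has noise SD ~ sqrt(1/40 + 1/72) percent
  ## per session, so truth is recovered on the cohort average
  cfg <- simConfig(nSubjects = 50, nSnps = 10, nCausal = 1, seed = 10)
  co <- simulateBoldCohort(cfg)
  bscMat <- vapply(co$sessions, function(s) percentBSC(s, "ambiguous"),
                   numeric(25))
  truth <- ts@bscTruth$ambiguous
  expect_lt(max(abs(rowMeans(bscMat) - truth)), 3 * 0.2 / sqrt(50) + 0.02)
  bsc <- percentBSC(ts, "ambiguous")
  ## equal condition and control means give zero
  flat <- ts
  flat@signal[] <- 50
  expect_equal(unname(percentBSC(flat, "ambiguous")), rep(0, 25))
  ## doubling the activation amplitude doubles the contrast numerator
  mkDet <- function(amp) {
    det <- ts
    det@signal[] <- 100
    starts <- which(det@design == "ambiguous")
    starts <- starts[c(TRUE, diff(starts) != 1)]
    for (s in starts) det@signal[(s + 2):(s + 9), 1] <-
      det@signal[(s + 2):(s + 9), 1] + amp
    det
  }
  b1 <- percentBSC(mkDet(1), "ambiguous")[1]
  b2 <- percentBSC(mkDet(2), "ambiguous")[1]
  run1 <- colMeans(mkDet(1)@signal[, 1, drop = FALSE])
  run2 <- colMeans(mkDet(2)@signal[, 1, drop = FALSE])
  expect_equal(unname(b2 * run2), unname(2 * b1 * run1), tolerance = 1e-10)
})

test_that("site-wise standardization removes injected scanner offsets", {
  cfg <- simConfig(nSubjects = 600, nSnps = 50, nCausal = 5,
                   targetH2 = 0.3, siteSd = 1.5, seed = 11)
  g <- simulateGenotypes(cfg)
  ph <- simulateMultiRoiPhenotypes(g, cfg, seed = NULL)
  roi <- faceRoiNames()[1]
  ## raw phenotypes show a big between-site variance
  rawF <- anova(lm(ph[[roi]] ~ factor(ph$site)))
  z <- standardizePhenotypes(ph)
  for (s in unique(z$site)) {
    expect_lt(abs(mean(z[z$site == s, roi])), 1e-12)
    expect_equal(sd(z[z$site == s, roi]), 1, tolerance = 1e-12)
  }
  zF <- anova(lm(z[[roi]] ~ factor(z$site)))
  expect_lt(zF$`Sum Sq`[1], 1e-12)
  expect_gt(rawF$`Sum Sq`[1], zF$`Sum Sq`[1])
  ## single site reduces to a plain z-score
  one <- ph[ph$site == 1, ]
  zi <- standardizePhenotypes(one)
  expect_equal(zi[[roi]], drop(scale(one[[roi]])), ignore_attr = TRUE)
})

test_that("population degree statistics and proportions summarise graphs", {
  r <- diag(3)
  mk <- function(edges) {
    m <- diag(3)
    for (e in edges) { m[e[1], e[2]] <- m[e[2], e[1]] <- 0.9 }
    thresholdAndDegree(m)
  }
  gA <- mk(list(c(1, 2)))
  gB <- mk(list(c(1, 2), c(1, 3)))
  stats <- degreePopulationStats(list(gA, gB))
  expect_equal(stats$mean, c(1.5, 1, 0.5))
  expect_equal(stats$sd, c(sd(c(1, 2)), 0, sd(c(0, 1))))
  expect_identical(dim(stats), c(3L, 3L))
  ## identical graphs across subjects: SD zero
  statsSame <- degreePopulationStats(list(gA, gA, gA))
  expect_true(all(statsSame$sd == 0))

  prop <- connectionProportions(list(gA, gB))
  expect_equal(prop[1, 2], 1)           # edge in every subject
  expect_equal(prop[1, 3], 0.5)
  expect_equal(diag(prop), rep(1, 3), ignore_attr = TRUE)
  expect_identical(prop, t(prop))
  expect_true(all(prop >= 0 & prop <= 1))
})
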