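## Second-level statistics: the Monte-Carlo correlated count-statistic null,
## trend regressions linking heritability to network properties, subnetwork
## classification, and split-half reproducibility.

#' Expected number of false positives
#'
#' Under the global null, `nTests * alpha` tests are significant by chance:
#' 1.25 for 25 tests at alpha = 0.05, 2.5 for 50.
#'
#' @param nTests number of tests.
#' @param alpha per-test significance level.
#' @return the expectation.
#' @export
expectedFalsePositives <- function(nTests, alpha) {
  stopifnot(nTests >= 0, alpha >= 0, alpha <= 1)
  nTests * alpha
}

.nearPSD <- function(corr) {
  ev <- eigen(corr, symmetric = TRUE)
  if (min(ev$values) >= -1e-8) return(corr)
  warning("correlation matrix is not PSD: nearest-PSD repair applied")
  v <- pmax(ev$values, 1e-8)
  m <- ev$vectors %*% (t(ev$vectors) * v)
  d <- sqrt(diag(m))
  m / tcrossprod(d)
}

#' Monte-Carlo null for the count of significant tests
#'
#' Draws `nRealizations` multivariate-normal vectors with the phenotypic
#' correlation of the per-ROI outcomes, converts each coordinate to a null
#' p-value, counts coordinates with p < alpha, and tabulates the count. The
#' reported p-value is the add-one estimate
#' (1 + #\{count >= observed\}) / (1 + nRealizations), so a count of 0 always
#' gets p = 1.
#'
#' @param corr symmetric unit-diagonal correlation matrix of the per-ROI
#'   outcomes (nearest-PSD repair applied with a warning if needed).
#' @param observedCount observed number of significant tests, in 0..nrow(corr).
#' @param alpha per-test level (default 0.05).
#' @param nRealizations Monte-Carlo draws (default 50000).
#' @param seed RNG seed.
#' @param mechanism `"normal"` converts each z to a two-sided normal p;
#'   `"mixture"` tests max(z, 0)^2 against the 50:50 point-mass/chi-square(1)
#'   boundary null, mirroring the variance-component LRT.
#' @return A \linkS4class{CountNullDistribution}.
#' @examples
#' mcCountPvalue(diag(25), observedCount = 3, nRealizations = 2000, seed = 1)
#' @export
mcCountPvalue <- function(corr, observedCount, alpha = 0.05,
                          nRealizations = 50000, seed = 1,
                          mechanism = c("normal", "mixture")) {
  mechanism <- match.arg(mechanism)
  k <- nrow(corr)
  observedCount <- as.integer(observedCount)
  if (observedCount < 0L || observedCount > k)
    stop("observedCount must lie in [0, ", k, "]")
  corr <- .nearPSD((corr + t(corr)) / 2)
  set.seed(seed)
  L <- chol(corr + diag(1e-10, k))
  z <- matrix(rnorm(nRealizations * k), nRealizations, k) %*% L
  pmat <- if (mechanism == "normal") {
    2 * pnorm(-abs(z))
  } else {
    stat <- pmax(z, 0)^2
    ifelse(stat == 0, 1, 0.5 * pchisq(stat, df = 1, lower.tail = FALSE))
  }
  counts <- rowSums(pmat < alpha)
  hist <- tabulate(counts + 1L, nbins = k + 1L)
  names(hist) <- 0:k
  pval <- (1 + sum(counts >= observedCount)) / (1 + nRealizations)
  new("CountNullDistribution", alpha = alpha,
      nRealizations = as.integer(nRealizations),
      histogram = as.integer(hist) |> setNames(names(hist)),
      observedCount = observedCount, pValue = pval, mechanism = mechanism)
}

.trendFit <- function(fit) {
  sm <- summary(fit)
  fs <- sm$fstatistic
  new("TrendFit", coefficients = coef(fit), r2 = sm$r.squared,
      fstat = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
      pValue = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))
}

#' Linear trend across ROIs
#'
#' OLS of a per-ROI response on a per-ROI predictor, with R-squared and the
#' overall F(1, n-2) test.
#'
#' @param x,y per-ROI predictor and response.
#' @return A \linkS4class{TrendFit}.
#' @export
fitLinearTrend <- function(x, y) {
  .trendFit(lm(y ~ x))
}

#' Quadratic trend across ROIs
#'
#' OLS on [1, x, x^2] with the overall F(2, n-3) test; for 25 ROIs the
#' denominator degrees of freedom are 22. Captures the inverted-U
#' relationships between degree variance, degree mean and response
#' amplitude.
#'
#' @inheritParams fitLinearTrend
#' @return A \linkS4class{TrendFit}.
#' @export
fitQuadraticTrend <- function(x, y) {
  .trendFit(lm(y ~ x + I(x^2)))
}

#' Classify ROIs into Optional / Obligatory subnetworks
#'
#' Default rule, with every quantile an explicit parameter: Optional ROIs
#' are the top `kOptional` by degree SD among ROIs whose degree mean lies
#' within the interquartile band of means (high inter-individual variability,
#' intermediate mean); Obligatory ROIs are the top `kObligatory` by degree
#' mean among the lowest-`sdTertile` fraction of SDs (consistently connected,
#' low variability). Ties break by ROI index. Degenerate (all-identical)
#' statistics give all-`Neither` labels with a warning.
#'
#' @param stats data.frame from [degreePopulationStats()] (`roi`, `mean`,
#'   `sd`).
#' @param kOptional,kObligatory subnetwork sizes (default 4 each).
#' @param meanBand quantile band of means admitting Optional candidates
#'   (default the interquartile band `c(0.25, 0.75)`).
#' @param sdTertile quantile of SDs admitting Obligatory candidates
#'   (default 1/3).
#' @return A \linkS4class{SubnetworkLabels}.
#' @export
classifySubnetworks <- function(stats, kOptional = 4, kObligatory = 4,
                                meanBand = c(0.25, 0.75), sdTertile = 1 / 3) {
  labels <- setNames(rep("Neither", nrow(stats)), stats$roi)
  params <- list(kOptional = kOptional, kObligatory = kObligatory,
                 meanBand = meanBand, sdTertile = sdTertile)
  if (sd(stats$mean) < 1e-12 && sd(stats$sd) < 1e-12) {
    warning("degenerate degree statistics: all ROIs identical, no labels")
    return(new("SubnetworkLabels", labels = labels, params = params))
  }
  qm <- quantile(stats$mean, meanBand)
  optCand <- which(stats$mean >= qm[1] & stats$mean <= qm[2])
  if (kOptional > length(optCand))
    stop("kOptional too large: at most ", length(optCand),
         " ROIs have an intermediate mean")
  opt <- optCand[order(-stats$sd[optCand], optCand)][seq_len(kOptional)]

  qs <- quantile(stats$sd, sdTertile)
  oblCand <- setdiff(which(stats$sd <= qs), opt)
  if (kObligatory > length(oblCand))
    stop("kObligatory too large: at most ", length(oblCand),
         " ROIs are in the low-SD band")
  obl <- oblCand[order(-stats$mean[oblCand], oblCand)][seq_len(kObligatory)]

  labels[opt] <- "Optional"
  labels[obl] <- "Obligatory"
  new("SubnetworkLabels", labels = labels, params = params)
}

#' Split-half reproducibility of per-ROI means
#'
#' Squared Pearson correlation of the per-ROI mean phenotypes between two
#' groups; an indirect index of measurement error in the absence of
#' test-retest data.
#'
#' @param meansA,meansB per-ROI mean phenotype in each group.
#' @return R-squared.
#' @export
splitHalfR2 <- function(meansA, meansB) {
  if (length(meansA) != length(meansB)) stop("ROI panels differ in length")
  cor(meansA, meansB)^2
}

#' Seeded random split-half R-squared
#'
#' Randomly halves the cohort (seeded), computes per-ROI mean phenotypes in
#' each half, and returns their squared correlation.
#'
#' @param pheno phenotype table with ROI columns (non-ROI columns `FID`,
#'   `IID`, `site`, `sex` are ignored).
#' @param seed RNG seed for the split.
#' @return list with `r2`, `nA`, `nB` and the two mean vectors.
#' @export
randomSplitHalfR2 <- function(pheno, seed = 1) {
  cols <- setdiff(names(pheno)[vapply(pheno, is.numeric, logical(1))],
                  c("site", "sex"))
  set.seed(seed)
  n <- nrow(pheno)
  a <- sort(sample.int(n, floor(n / 2)))
  b <- setdiff(seq_len(n), a)
  mA <- colMeans(pheno[a, cols, drop = FALSE])
  mB <- colMeans(pheno[b, cols, drop = FALSE])
  list(r2 = splitHalfR2(mA, mB), nA = length(a), nB = length(b),
       meansA = mA, meansB = mB)
}
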