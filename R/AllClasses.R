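#' @import methods
#' @importFrom stats coef cor lm median na.omit pchisq pf pnorm pt qchisq
#'   quantile rbinom rnorm runif sd var setNames
#' @importFrom utils read.table write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## GenotypeData: SNP dosages with per-SNP metadata, Bioconductor orientation
## (rows = SNPs, columns = samples)
## ---------------------------------------------------------------------------

#' Genotype container
#'
#' Minor-allele dosage matrix (SNPs x samples, values 0/1/2 or `NA` for
#' missing) stored as a \linkS4class{SummarizedExperiment} with per-SNP
#' metadata (`id`, `chrom`, `pos`, `a1`, `a2`, generating frequency `p` when
#' simulated) in `rowData` and sample identifiers (`FID`, `IID`) in `colData`.
#'
#' @aliases GenotypeData-class
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- NULL
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  need <- c("id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% colnames(rowData(object))))
    msg <- c(msg, sprintf("rowData must contain %s", paste(need, collapse = ", ")))
  if (!all(c("FID", "IID") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain FID and IID")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix, SNPs x samples, entries 0/1/2/`NA`.
#' @param snpMeta data.frame with columns `id`, `chrom`, `pos`, `a1`, `a2`
#'   (one row per SNP); a `p` column of generating frequencies is kept if present.
#' @param sampleIds data.frame with columns `FID`, `IID` (one row per sample).
#' @return A \linkS4class{GenotypeData}.
#' @export
GenotypeData <- function(dosage, snpMeta, sampleIds) {
  dosage <- as.matrix(dosage)
  rownames(dosage) <- snpMeta$id
  colnames(dosage) <- sampleIds$IID
  se <- SummarizedExperiment(
    assays  = list(dosage = dosage),
    rowData = DataFrame(snpMeta),
    colData = DataFrame(sampleIds))
  new("GenotypeData", se)
}

#' @describeIn GenotypeData dosage matrix (SNPs x samples)
#' @param x,object a `GenotypeData`
#' @export
dosages <- function(x) assay(x, "dosage")

#' @describeIn GenotypeData per-SNP metadata as a data.frame
#' @export
snpMeta <- function(x) as.data.frame(rowData(x))

#' Sample identifiers
#'
#' @param x a `GenotypeData` or `GRM`
#' @return data.frame with columns `FID`, `IID`.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "GenotypeData", function(x)
  as.data.frame(colData(x))[, c("FID", "IID"), drop = FALSE])

#' Observed minor-allele frequencies
#'
#' Allele frequencies computed on non-missing calls, `colMeans`-style:
#' half the mean dosage per SNP.
#'
#' @param x a `GenotypeData`
#' @return numeric vector, one frequency per SNP.
#' @export
alleleFreq <- function(x) {
  rowMeans(dosages(x), na.rm = TRUE) / 2
}

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d SNPs x %d samples, %.3f%% missing\n",
              nrow(object), ncol(object),
              100 * mean(is.na(assay(object, "dosage")))))
})

## ---------------------------------------------------------------------------
## GRM
## ---------------------------------------------------------------------------

#' Genomic relationship matrix
#'
#' Symmetric n x n relatedness matrix in GCTA conventions, together with the
#' per-pair count of SNPs used and the sample identifiers.
#'
#' @slot values symmetric numeric matrix of relatedness coefficients.
#' @slot nsnp integer matrix, per-pair count of non-missing SNPs.
#' @slot sampleIds data.frame with `FID`, `IID`.
#' @aliases GRM-class
#' @export
setClass("GRM", representation(
  values = "matrix", nsnp = "matrix", sampleIds = "data.frame"))

setValidity("GRM", function(object) {
  v <- object@values
  msg <- NULL
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (!all(is.finite(v))) msg <- c(msg, "values must be finite")
  if (nrow(v) && max(abs(v - t(v))) > 1e-8) msg <- c(msg, "values must be symmetric")
  if (!identical(dim(object@nsnp), dim(v))) msg <- c(msg, "nsnp dimension mismatch")
  if (nrow(object@sampleIds) != nrow(v)) msg <- c(msg, "sampleIds length mismatch")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn GRM relatedness matrix
#' @param x,object a `GRM`
#' @export
grmValues <- function(x) x@values

#' @describeIn GRM per-pair SNP counts
#' @export
grmNsnp <- function(x) x@nsnp

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "GRM", function(x) x@sampleIds)

setMethod("show", "GRM", function(object) {
  n <- nrow(object@values)
  od <- object@values[upper.tri(object@values)]
  cat(sprintf("GRM: %d samples; mean diagonal %.4f; off-diagonal range [%.4f, %.4f]\n",
              n, mean(diag(object@values)),
              if (length(od)) min(od) else NA_real_,
              if (length(od)) max(od) else NA_real_))
})

#' @describeIn GRM number of samples
#' @export
setMethod("dim", "GRM", function(x) dim(x@values))

## ---------------------------------------------------------------------------
## QcReport
## ---------------------------------------------------------------------------

#' Quality-control report
#'
#' Records, per filter and in application order, how many SNPs or samples
#' each filter removed, plus the thresholds used.
#'
#' @slot removed named integer vector, one entry per filter in order applied.
#' @slot nInput,nRetained item counts before and after.
#' @slot thresholds named list of thresholds used.
#' @slot unit "SNPs" or "samples".
#' @aliases QcReport-class
#' @export
setClass("QcReport", representation(
  removed = "integer", nInput = "integer", nRetained = "integer",
  thresholds = "list", unit = "character"))

setValidity("QcReport", function(object) {
  if (sum(object@removed) + object@nRetained != object@nInput)
    "removed + retained must equal input" else TRUE
})

setMethod("show", "QcReport", function(object) {
  cat(sprintf("QcReport (%s): %d in, %d retained\n",
              object@unit, object@nInput, object@nRetained))
  for (f in names(object@removed))
    cat(sprintf("  %-12s removed %d\n", f, object@removed[[f]]))
})

## ---------------------------------------------------------------------------
## Variance-component results
## ---------------------------------------------------------------------------

#' Univariate REML variance components
#'
#' Result of fitting y = Xb + g + e with var(g) = A*VG, var(e) = I*VE by
#' average-information REML.
#'
#' @slot VG,VE,Vp variance components (Vp = VG + VE).
#' @slot ratio VG/Vp, the SNP-based heritability estimate.
#' @slot seRatio delta-method standard error of the ratio.
#' @slot seVG,seVE standard errors from the inverse AI matrix.
#' @slot logL restricted log-likelihood at the optimum.
#' @slot nIter iterations used.
#' @slot converged,constrained status flags.
#' @aliases VarianceComponents-class
#' @export
setClass("VarianceComponents", representation(
  VG = "numeric", VE = "numeric", Vp = "numeric", ratio = "numeric",
  seRatio = "numeric", seVG = "numeric", seVE = "numeric",
  logL = "numeric", nIter = "integer",
  converged = "logical", constrained = "logical"))

setValidity("VarianceComponents", function(object) {
  msg <- NULL
  if (object@Vp <= 0) msg <- c(msg, "Vp must be positive")
  if (object@ratio < -1e-8 || object@ratio > 1 + 1e-8)
    msg <- c(msg, "ratio must lie in [0,1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(
    "VarianceComponents: VG/Vp = %.4f (SE %.4f), VG = %.4f, VE = %.4f, logL = %.4f\n",
    object@ratio, object@seRatio, object@VG, object@VE, object@logL))
  cat(sprintf("  %d iterations; converged: %s; constrained: %s\n",
              object@nIter, object@converged, object@constrained))
})

#' Likelihood-ratio test result under the boundary mixture null
#'
#' @slot statistic 2*(logL_full - logL_null), clamped at 0.
#' @slot df nominal degrees of freedom (1).
#' @slot pValue probability under the 50:50 point-mass/chi-square(1) mixture.
#' @aliases LrtResult-class
#' @export
setClass("LrtResult", representation(
  statistic = "numeric", df = "numeric", pValue = "numeric"))

setValidity("LrtResult", function(object) {
  msg <- NULL
  if (object@statistic < 0) msg <- c(msg, "statistic must be >= 0")
  if (object@pValue < 0 || object@pValue > 1) msg <- c(msg, "p must be in [0,1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "LrtResult", function(object) {
  cat(sprintf("LRT: statistic = %.4f (df = %g), mixture-null p = %.4g\n",
              object@statistic, object@df, object@pValue))
})

#' Bivariate REML components
#'
#' Six variance/covariance components for a pair of traits sharing one GRM,
#' with the genetic correlation rG = covG / sqrt(VG1*VG2).
#'
#' @slot VG1,VG2,covG genetic (co)variances.
#' @slot VE1,VE2,covE residual (co)variances.
#' @slot rG,seRG genetic correlation and its delta-method SE.
#' @slot pCovG Wald p-value for covG = 0.
#' @slot logL restricted log-likelihood.
#' @slot converged,unstable status flags (`unstable` set when either VG sits
#'   at the boundary, making rG ill-defined).
#' @aliases BivariateComponents-class
#' @export
setClass("BivariateComponents", representation(
  VG1 = "numeric", VG2 = "numeric", covG = "numeric",
  VE1 = "numeric", VE2 = "numeric", covE = "numeric",
  rG = "numeric", seRG = "numeric", pCovG = "numeric",
  logL = "numeric", nIter = "integer",
  converged = "logical", unstable = "logical"))

setMethod("show", "BivariateComponents", function(object) {
  cat(sprintf("BivariateComponents: rG = %.4f (SE %.4f), covG = %.4f (Wald p = %.3g)\n",
              object@rG, object@seRG, object@covG, object@pCovG))
  if (object@unstable) cat("  [unstable: a genetic variance is at the boundary]\n")
})

## ---------------------------------------------------------------------------
## BOLD time series and connectivity graphs
## ---------------------------------------------------------------------------

#' Single-subject ROI time series
#'
#' Block-design BOLD session: a volumes x channels signal matrix (ROI
#' channels plus `WM` and `CSF` nuisance channels), per-volume block labels,
#' and the repetition time.
#'
#' @slot subjectId subject identifier.
#' @slot signal numeric matrix, volumes x channels, named columns.
#' @slot design character vector of per-volume labels
#'   (`ambiguous`, `angry`, `control`, `rest`).
#' @slot trSeconds repetition time in seconds (2.2 for the emulated design).
#' @slot bscTruth named per-ROI ground-truth percent signal change per face
#'   condition (simulated sessions only; empty otherwise).
#' @aliases RoiTimeSeries-class
#' @export
setClass("RoiTimeSeries", representation(
  subjectId = "character", signal = "matrix", design = "character",
  trSeconds = "numeric", bscTruth = "list"))

setValidity("RoiTimeSeries", function(object) {
  msg <- NULL
  if (nrow(object@signal) != length(object@design))
    msg <- c(msg, "design length must equal number of volumes")
  if (!all(object@design %in% c("ambiguous", "angry", "control", "rest")))
    msg <- c(msg, "labels must be ambiguous/angry/control/rest")
  if (is.null(colnames(object@signal)))
    msg <- c(msg, "signal columns must be named")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries '%s': %d volumes x %d channels (TR %.1f s)\n",
              object@subjectId, nrow(object@signal), ncol(object@signal),
              object@trSeconds))
  cat("  blocks:", paste(sprintf("%s=%d", names(table(object@design)),
                                 table(object@design)), collapse = ", "), "\n")
})

#' Names of ROI channels (everything except WM/CSF)
#' @param ts a `RoiTimeSeries`
#' @export
roiChannels <- function(ts) {
  setdiff(colnames(ts@signal), c("WM", "CSF"))
}

#' Condition-specific functional-connectivity graph
#'
#' @slot condition face condition the graph belongs to.
#' @slot corr symmetric ROI x ROI Pearson correlation matrix, unit diagonal.
#' @slot adjacency logical matrix, `corr > threshold` off the diagonal.
#' @slot degree per-ROI edge count.
#' @slot threshold correlation threshold used (strict inequality).
#' @aliases ConnectivityGraph-class
#' @export
setClass("ConnectivityGraph", representation(
  condition = "character", corr = "matrix", adjacency = "matrix",
  degree = "integer", threshold = "numeric"))

setValidity("ConnectivityGraph", function(object) {
  msg <- NULL
  k <- nrow(object@corr)
  if (max(abs(object@corr - t(object@corr))) > 1e-8)
    msg <- c(msg, "corr must be symmetric")
  if (max(abs(diag(object@corr) - 1)) > 1e-8)
    msg <- c(msg, "corr must have unit diagonal")
  if (any(diag(object@adjacency) != 0))
    msg <- c(msg, "adjacency diagonal must be zero")
  if (!identical(object@degree, as.integer(rowSums(object@adjacency))))
    msg <- c(msg, "degree must equal adjacency row sums")
  if (any(object@degree > k - 1)) msg <- c(msg, "degree exceeds node count - 1")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ConnectivityGraph per-ROI degree vector
#' @param x,object a `ConnectivityGraph`
#' @export
degree <- function(x) x@degree

#' @describeIn ConnectivityGraph boolean adjacency matrix
#' @export
adjacency <- function(x) x@adjacency

setMethod("show", "ConnectivityGraph", function(object) {
  cat(sprintf("ConnectivityGraph (%s): %d ROIs, %d edges at r > %.2f\n",
              object@condition, nrow(object@corr),
              sum(object@adjacency) / 2, object@threshold))
})

## ---------------------------------------------------------------------------
## Second-level inference containers
## ---------------------------------------------------------------------------

#' Monte-Carlo null distribution of the count of significant tests
#'
#' @slot alpha per-test significance level.
#' @slot nRealizations Monte-Carlo sample size.
#' @slot histogram named counts over 0..k significant tests.
#' @slot observedCount the observed count the p-value refers to.
#' @slot pValue add-one estimate of P(count >= observed) under the null.
#' @slot mechanism "normal" (two-sided z) or "mixture" (boundary LRT null).
#' @aliases CountNullDistribution-class
#' @export
setClass("CountNullDistribution", representation(
  alpha = "numeric", nRealizations = "integer", histogram = "integer",
  observedCount = "integer", pValue = "numeric", mechanism = "character"))

setValidity("CountNullDistribution", function(object) {
  msg <- NULL
  if (sum(object@histogram) != object@nRealizations)
    msg <- c(msg, "histogram must sum to nRealizations")
  if (object@pValue < 0 || object@pValue > 1) msg <- c(msg, "p must be in [0,1]")
  if (object@observedCount == 0L && object@pValue != 1)
    msg <- c(msg, "p must be 1 for a count of 0")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CountNullDistribution", function(object) {
  cat(sprintf(
    "CountNullDistribution: observed %d significant at alpha=%.3g, MC p = %.4g (%d draws, %s nulls)\n",
    object@observedCount, object@alpha, object@pValue,
    object@nRealizations, object@mechanism))
})

#' Polynomial trend fit across ROIs
#'
#' @slot coefficients named OLS coefficients.
#' @slot r2 coefficient of determination.
#' @slot fstat overall F statistic with degrees `df1`, `df2`.
#' @slot pValue p-value of the overall F test.
#' @aliases TrendFit-class
#' @export
setClass("TrendFit", representation(
  coefficients = "numeric", r2 = "numeric", fstat = "numeric",
  df1 = "numeric", df2 = "numeric", pValue = "numeric"))

setValidity("TrendFit", function(object) {
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12) "R2 must be in [0,1]" else TRUE
})

setMethod("show", "TrendFit", function(object) {
  cat(sprintf("TrendFit: R2 = %.3f, F(%g,%g) = %.3f, p = %.4g\n",
              object@r2, object@df1, object@df2, object@fstat, object@pValue))
})

#' Subnetwork labels for the face-network ROIs
#'
#' @slot labels named character vector, each `Obligatory`, `Optional` or
#'   `Neither`.
#' @slot params the rule parameters used, recorded for reproducibility.
#' @aliases SubnetworkLabels-class
#' @export
setClass("SubnetworkLabels", representation(
  labels = "character", params = "list"))

setValidity("SubnetworkLabels", function(object) {
  if (!all(object@labels %in% c("Obligatory", "Optional", "Neither")))
    "labels must be Obligatory/Optional/Neither" else TRUE
})

setMethod("show", "SubnetworkLabels", function(object) {
  for (lab in c("Optional", "Obligatory")) {
    m <- names(object@labels)[object@labels == lab]
    cat(sprintf("%-10s: %s\n", lab,
                if (length(m)) paste(m, collapse = ", ") else "(none)"))
  }
})
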