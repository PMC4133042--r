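## Synthetic cohort generator: genotypes under Hardy-Weinberg sampling,
## polygenic multi-ROI phenotypes with a known VG/Vp, and block-design BOLD
## sessions whose inter-ROI correlations are governed by per-pair connection
## probabilities. Every downstream stage is testable against this ground truth.

.ROI_NAMES <- c(
  "MVLFC_L", "MVLFC_R", "MDLFC_L", "MDLFC_R", "PMC_L", "PMC_R", "PreSMA_R",
  "Rhinal_L", "Rhinal_R", "Amygdala_L", "Amygdala_R", "AntSTS_L", "AntSTS_R",
  "PostSTS_L", "PostSTS_R", "FFA_L", "FFA_R", "LOC_L", "LOC_R",
  "V2V3_L", "V2V3_R", "Cerebellum_L", "Cerebellum_R", "Putamen_L", "Putamen_R")

## population mean %BSC per ROI in the ambiguous contrast (used as simulation
## ground truth so amplitudes span the realistic 0.2-0.7% range)
.ROI_BSC_MEAN <- setNames(
  c(0.35, 0.43, 0.40, 0.56, 0.37, 0.44, 0.37, 0.17, 0.23, 0.37, 0.50, 0.27,
    0.44, 0.52, 0.73, 0.54, 0.64, 0.47, 0.58, 0.37, 0.37, 0.45, 0.22, 0.25,
    0.33),
  .ROI_NAMES)

## observed connection proportions among the eight Optional/Obligatory ROIs
.SUBNET_ROIS <- c("MVLFC_R", "MDLFC_L", "PMC_L", "AntSTS_R",
                  "PostSTS_R", "FFA_R", "LOC_L", "LOC_R")
.SUBNET_PROB <- matrix(c(
  1.00, 0.56, 0.30, 0.54, 0.61, 0.28, 0.30, 0.27,
  0.56, 1.00, 0.60, 0.35, 0.45, 0.35, 0.31, 0.32,
  0.30, 0.60, 1.00, 0.31, 0.49, 0.45, 0.48, 0.51,
  0.54, 0.35, 0.31, 1.00, 0.65, 0.47, 0.37, 0.37,
  0.61, 0.45, 0.49, 0.65, 1.00, 0.78, 0.69, 0.75,
  0.28, 0.35, 0.45, 0.47, 0.78, 1.00, 0.85, 0.89,
  0.30, 0.31, 0.48, 0.37, 0.69, 0.85, 1.00, 0.95,
  0.27, 0.32, 0.51, 0.37, 0.75, 0.89, 0.95, 1.00),
  nrow = 8, dimnames = list(.SUBNET_ROIS, .SUBNET_ROIS))

#' Face-network ROI names
#'
#' The 25 regions of the face-processing network used throughout the package
#' (bilateral frontal, temporal, occipital, subcortical and cerebellar nodes
#' plus the right pre-SMA).
#'
#' @return character vector of length 25.
#' @export
faceRoiNames <- function() .ROI_NAMES

#' Default per-pair connection probabilities
#'
#' Symmetric 25 x 25 matrix of probabilities that a given ROI pair is
#' functionally connected (pairwise r > 0.3) in a given subject. The eight
#' Optional/Obligatory subnetwork ROIs carry the observed population
#' proportions; every other pair defaults to `background`.
#'
#' @param background probability for pairs outside the eight-ROI subnetwork
#'   block (default 0.4, mid-range of the observed proportions).
#' @return numeric matrix with unit diagonal.
#' @export
defaultConnectionProb <- function(background = 0.4) {
  stopifnot(background >= 0, background <= 1)
  p <- matrix(background, 25, 25, dimnames = list(.ROI_NAMES, .ROI_NAMES))
  p[.SUBNET_ROIS, .SUBNET_ROIS] <- .SUBNET_PROB
  diag(p) <- 1
  p
}

#' Standard block design
#'
#' Per-volume labels for the emulated 160-volume session at TR 2.2 s:
#' 19 task blocks of 8 volumes (9 control interleaved with 5 ambiguous and
#' 5 angry face blocks) followed by 8 rest volumes.
#'
#' @return character vector of length 160.
#' @export
defaultBlockDesign <- function() {
  faces <- rep(c("ambiguous", "angry"), 5)
  blocks <- character(0)
  for (i in 1:9) blocks <- c(blocks, "control", faces[i])
  blocks <- c(blocks, faces[10])
  c(rep(blocks, each = 8), rep("rest", 8))
}

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Holds every knob of the synthetic cohort. Defaults state the emulated
#' study: 1,620 unrelated subjects, a scaled-down independent SNP panel,
#' polygenic phenotypes at the high heritability the design can estimate
#' (VG/Vp = 0.5), 25 ROIs, the 160-volume block design, and connection
#' probabilities anchored on the observed subnetwork proportions.
#'
#' @slot nSubjects,nSnps cohort and panel size.
#' @slot mafRange generating minor-allele frequency range, in (0, 0.5].
#' @slot nCausal number of causal SNPs per ROI phenotype.
#' @slot targetH2 generating VG/Vp in [0, 1].
#' @slot missingRate genotype missingness rate in [0, 1).
#' @slot roiCount,roiNames number and names of ROIs.
#' @slot roiPhenoCorr ROI x ROI environmental correlation (symmetric PSD,
#'   unit diagonal).
#' @slot blockDesign per-volume labels over the 160 volumes.
#' @slot pairConnectionProb symmetric per-pair connection probabilities.
#' @slot coupling expected block-concatenated correlation of a connected pair.
#' @slot noiseSd,baseline BOLD noise SD and baseline, in signal units.
#' @slot wmLeak,csfLeak nuisance-channel leakage coefficients into ROI signals.
#' @slot bscAmbiguous,bscAngry per-ROI ground-truth percent signal change.
#' @slot nSites,siteSd,sexEffect acquisition-site count, SD of the additive
#'   per-site offset, and additive sex effect on the phenotype.
#' @slot trSeconds repetition time, seconds.
#' @slot seed integer seed.
#' @aliases SimConfig-class
#' @export
setClass("SimConfig", representation(
  nSubjects = "integer", nSnps = "integer", mafRange = "numeric",
  nCausal = "integer", targetH2 = "numeric", missingRate = "numeric",
  roiCount = "integer", roiNames = "character", roiPhenoCorr = "matrix",
  blockDesign = "character", pairConnectionProb = "matrix",
  coupling = "numeric", noiseSd = "numeric", baseline = "numeric",
  wmLeak = "numeric", csfLeak = "numeric",
  bscAmbiguous = "numeric", bscAngry = "numeric",
  nSites = "integer", siteSd = "numeric", sexEffect = "numeric",
  trSeconds = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- NULL
  if (object@nSubjects < 2L) msg <- c(msg, "nSubjects must be >= 2")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  mr <- object@mafRange
  if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    msg <- c(msg, "mafRange must lie in (0, 0.5]")
  if (object@targetH2 < 0 || object@targetH2 > 1)
    msg <- c(msg, "targetH2 must be in [0, 1]")
  if (object@nCausal > object@nSnps) msg <- c(msg, "nCausal must be <= nSnps")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  R <- object@roiCount
  cc <- object@roiPhenoCorr
  if (!identical(dim(cc), c(R, R) * 1L) && !identical(dim(cc), as.integer(c(R, R))))
    msg <- c(msg, "roiPhenoCorr must be roiCount x roiCount")
  else {
    if (max(abs(cc - t(cc))) > 1e-8) msg <- c(msg, "roiPhenoCorr must be symmetric")
    if (max(abs(diag(cc) - 1)) > 1e-8)
      msg <- c(msg, "roiPhenoCorr must have unit diagonal")
    if (min(eigen(cc, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      msg <- c(msg, "roiPhenoCorr must be positive semi-definite")
  }
  if (length(object@roiNames) != R) msg <- c(msg, "roiNames length mismatch")
  pcp <- object@pairConnectionProb
  if (!identical(dim(pcp), as.integer(c(R, R))))
    msg <- c(msg, "pairConnectionProb must be roiCount x roiCount")
  else if (any(pcp < 0 | pcp > 1))
    msg <- c(msg, "pairConnectionProb entries must be in [0, 1]")
  if (length(object@blockDesign) != 160L)
    msg <- c(msg, "blockDesign must cover exactly 160 volumes")
  if (!all(object@blockDesign %in% c("ambiguous", "angry", "control", "rest")))
    msg <- c(msg, "blockDesign labels must be ambiguous/angry/control/rest")
  if (object@coupling < 0 || object@coupling >= 1)
    msg <- c(msg, "coupling must be in [0, 1)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a simulation configuration
#'
#' @param nSubjects,nSnps cohort and SNP-panel size (defaults 1620 and 20000,
#'   the emulated cohort with the panel scaled down from ~500K genotyped SNPs).
#' @param mafRange generating allele-frequency range (default `c(0.05, 0.5)`).
#' @param nCausal causal SNPs per phenotype (default 200).
#' @param targetH2 generating VG/Vp (default 0.5).
#' @param missingRate genotype missingness rate (default 0).
#' @param roiCount,roiNames ROI panel (defaults: the 25 face-network ROIs).
#' @param roiPhenoCorr environmental inter-ROI correlation (default
#'   exchangeable at 0.3).
#' @param blockDesign per-volume labels (default [defaultBlockDesign()]).
#' @param pairConnectionProb per-pair connection probabilities (default
#'   [defaultConnectionProb()]).
#' @param coupling expected correlation of connected pairs over the
#'   concatenated task blocks (default 0.5, above the 0.3 edge threshold).
#' @param noiseSd,baseline BOLD noise SD and baseline (defaults 1 and 100).
#' @param wmLeak,csfLeak nuisance leakage into ROI channels (defaults 0).
#' @param bscAmbiguous,bscAngry per-ROI ground-truth percent signal change
#'   (defaults: the observed ambiguous-contrast population means for both).
#' @param nSites,siteSd number of acquisition sites (default 8) and the SD of
#'   the additive per-site offset (default 0.3 phenotype SD units).
#' @param sexEffect additive male-female phenotype difference (default 0.1).
#' @param trSeconds repetition time (default 2.2 s).
#' @param seed integer seed (default 1).
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nSubjects = 100, nSnps = 500, nCausal = 50)
#' @export
simConfig <- function(nSubjects = 1620, nSnps = 20000,
                      mafRange = c(0.05, 0.5), nCausal = 200,
                      targetH2 = 0.5, missingRate = 0,
                      roiCount = 25, roiNames = NULL,
                      roiPhenoCorr = NULL, blockDesign = defaultBlockDesign(),
                      pairConnectionProb = NULL, coupling = 0.5,
                      noiseSd = 1, baseline = 100, wmLeak = 0, csfLeak = 0,
                      bscAmbiguous = NULL, bscAngry = NULL,
                      nSites = 8, siteSd = 0.3, sexEffect = 0.1,
                      trSeconds = 2.2, seed = 1) {
  roiCount <- as.integer(roiCount)
  if (is.null(roiNames)) {
    roiNames <- if (roiCount == 25L) .ROI_NAMES else
      sprintf("ROI%02d", seq_len(roiCount))
  }
  if (is.null(roiPhenoCorr)) {
    roiPhenoCorr <- matrix(0.3, roiCount, roiCount)
    diag(roiPhenoCorr) <- 1
  }
  if (is.null(pairConnectionProb)) {
    pairConnectionProb <- if (roiCount == 25L) defaultConnectionProb() else {
      p <- matrix(0.4, roiCount, roiCount); diag(p) <- 1; p
    }
  }
  if (is.null(bscAmbiguous)) {
    bscAmbiguous <- if (roiCount == 25L) unname(.ROI_BSC_MEAN) else
      rep(0.4, roiCount)
  }
  if (is.null(bscAngry)) bscAngry <- bscAmbiguous
  new("SimConfig",
      nSubjects = as.integer(nSubjects), nSnps = as.integer(nSnps),
      mafRange = as.numeric(mafRange), nCausal = as.integer(nCausal),
      targetH2 = as.numeric(targetH2), missingRate = as.numeric(missingRate),
      roiCount = roiCount, roiNames = roiNames,
      roiPhenoCorr = unname(roiPhenoCorr), blockDesign = blockDesign,
      pairConnectionProb = unname(pairConnectionProb),
      coupling = as.numeric(coupling), noiseSd = as.numeric(noiseSd),
      baseline = as.numeric(baseline),
      wmLeak = as.numeric(wmLeak), csfLeak = as.numeric(csfLeak),
      bscAmbiguous = as.numeric(bscAmbiguous), bscAngry = as.numeric(bscAngry),
      nSites = as.integer(nSites), siteSd = as.numeric(siteSd),
      sexEffect = as.numeric(sexEffect), trSeconds = as.numeric(trSeconds),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d subjects, %d SNPs (MAF %.2f-%.2f), %d causal, h2 = %.2f, %d ROIs, seed %d\n",
    object@nSubjects, object@nSnps, object@mafRange[1], object@mafRange[2],
    object@nCausal, object@targetH2, object@roiCount, object@seed))
})

## ---------------------------------------------------------------------------
## Genotypes
## ---------------------------------------------------------------------------

#' Simulate genotypes under Hardy-Weinberg sampling
#'
#' Each SNP's generating frequency is drawn uniformly from `mafRange`; each
#' dosage is the sum of two independent Bernoulli(p) allele draws. Optional
#' missingness is injected completely at random.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed seed used for this draw; `NULL` continues the current RNG
#'   stream (default: the config seed).
#' @return A \linkS4class{GenotypeData} with the generating `p` recorded in
#'   `snpMeta()`.
#' @examples
#' g <- simulateGenotypes(simConfig(nSubjects = 20, nSnps = 50, nCausal = 10))
#' dim(dosages(g))
#' @export
simulateGenotypes <- function(config, seed = config@seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config@nSubjects; m <- config@nSnps
  p <- runif(m, config@mafRange[1], config@mafRange[2])
  ## prob recycles over the column-major fill, giving row i probability p[i]
  dosage <- matrix(rbinom(n * m, size = 2L, prob = p), nrow = m, ncol = n)
  if (config@missingRate > 0) {
    drop <- runif(n * m) < config@missingRate
    dosage[drop] <- NA_integer_
  }
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, m, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1))
  meta <- data.frame(
    id = sprintf("snp%06d", seq_len(m)), chrom = 1L,
    pos = seq_len(m) * 1000L, a1 = a1, a2 = unname(a2), p = p,
    stringsAsFactors = FALSE)
  ids <- data.frame(FID = sprintf("F%04d", seq_len(n)),
                    IID = sprintf("I%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  GenotypeData(dosage, meta, ids)
}

## ---------------------------------------------------------------------------
## Phenotypes
## ---------------------------------------------------------------------------

#' Simulate polygenic multi-ROI phenotypes
#'
#' For each ROI the phenotype is a sum of causal standardized-dosage effects
#' plus correlated environmental noise. Effects are drawn standard normal
#' and rescaled so the population VG/Vp equals `targetH2` exactly (phenotypic
#' variance 1 before site and sex effects). Environmental noise is drawn
#' multivariate normal with correlation `roiPhenoCorr` scaled to `1 - targetH2`.
#' Additive site offsets and a sex effect are layered on top for covariate
#' testing; both are removed downstream by per-site z-scoring and the sex
#' covariate.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param config a \linkS4class{SimConfig}.
#' @param effectSharing `"independent"` (each ROI draws its own effects on one
#'   shared causal set), `"shared"` (identical effects across ROIs, so the
#'   genetic correlation is 1 by construction) or `"disjoint"` (each ROI gets
#'   its own disjoint causal set, genetic correlation 0).
#' @param seed seed for this draw; `NULL` continues the RNG stream.
#' @return data.frame with columns `FID`, `IID`, `site`, `sex` and one column
#'   per ROI; attributes `causal` (per-ROI causal SNP ids) and
#'   `geneticValues` (n x ROI matrix of true breeding values).
#' @export
simulateMultiRoiPhenotypes <- function(genotypes, config,
                                       effectSharing = c("independent",
                                                         "shared", "disjoint"),
                                       seed = config@seed) {
  effectSharing <- match.arg(effectSharing)
  if (!is.null(seed)) set.seed(seed)
  d <- dosages(genotypes)
  m <- nrow(d); n <- ncol(d); R <- config@roiCount
  q <- config@nCausal
  if (q > m) stop("nCausal exceeds the number of simulated SNPs")
  h2 <- config@targetH2

  meta <- snpMeta(genotypes)
  p <- if ("p" %in% names(meta)) meta$p else rowMeans(d, na.rm = TRUE) / 2

  if (effectSharing == "disjoint") {
    if (q * R > m) stop("disjoint causal sets need nCausal * roiCount <= nSnps")
    pool <- sample.int(m, q * R)
    causalIdx <- split(pool, rep(seq_len(R), each = q))
  } else {
    shared <- sample.int(m, q)
    causalIdx <- rep(list(shared), R)
  }

  gmat <- matrix(0, n, R)
  causalIds <- vector("list", R)
  betaShared <- rnorm(q)
  for (r in seq_len(R)) {
    idx <- causalIdx[[r]]
    causalIds[[r]] <- meta$id[idx]
    beta <- if (effectSharing == "shared") betaShared else rnorm(q)
    if (h2 > 0) {
      beta <- beta * sqrt(h2 / sum(beta^2))
      w <- (d[idx, , drop = FALSE] - 2 * p[idx]) / sqrt(2 * p[idx] * (1 - p[idx]))
      w[is.na(w)] <- 0
      gmat[, r] <- drop(crossprod(w, beta))
    }
  }

  sigE <- (1 - h2) * config@roiPhenoCorr
  emat <- if (h2 < 1) {
    L <- tryCatch(chol(sigE + diag(1e-10, R)), error = function(e)
      stop("roiPhenoCorr is not positive semi-definite: Cholesky failed (",
           conditionMessage(e), ")"))
    matrix(rnorm(n * R), n, R) %*% L
  } else matrix(0, n, R)

  site <- sample(rep_len(seq_len(config@nSites), n))
  siteOffset <- rnorm(config@nSites, 0, config@siteSd)
  sex <- sample(c(1L, 2L), n, replace = TRUE)   # 1 = male, 2 = female (PED coding)

  y <- gmat + emat + siteOffset[site] + config@sexEffect * (sex == 1L)
  colnames(y) <- config@roiNames[seq_len(R)]

  ids <- sampleIds(genotypes)
  out <- data.frame(FID = ids$FID, IID = ids$IID, site = site, sex = sex,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(y))
  names(causalIds) <- colnames(y)
  attr(out, "causal") <- causalIds
  attr(out, "geneticValues") <- gmat
  out
}

## ---------------------------------------------------------------------------
## BOLD sessions
## ---------------------------------------------------------------------------

#' Draw per-subject connectivity graphs
#'
#' Each ROI pair is connected with its entry of `pairConnectionProb`,
#' independently across subjects.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param nSubjects number of graphs (default: the config cohort size).
#' @param seed seed; `NULL` continues the RNG stream.
#' @return list of symmetric logical adjacency matrices.
#' @export
simulateSubjectGraphs <- function(config, nSubjects = config@nSubjects,
                                  seed = config@seed) {
  if (!is.null(seed)) set.seed(seed)
  R <- config@roiCount
  ut <- upper.tri(matrix(0, R, R))
  pvec <- config@pairConnectionProb[ut]
  lapply(seq_len(nSubjects), function(s) {
    a <- matrix(FALSE, R, R,
                dimnames = list(config@roiNames, config@roiNames))
    a[ut] <- runif(length(pvec)) < pvec
    a | t(a)
  })
}

.blockStarts <- function(design, condition) {
  idx <- which(design == condition)
  if (!length(idx)) integer(0) else idx[c(TRUE, diff(idx) != 1)]
}

#' Simulate one block-design BOLD session
#'
#' Generates the 160-volume session. During task (face and control) blocks,
#' ROIs joined by an edge in `subjectGraph` draw their noise from a
#' multivariate normal whose pairwise correlation equals `coupling`, so the
#' expected correlation of the block-concatenated series equals `coupling`
#' (default 0.5, above the 0.3 edge threshold); unconnected pairs and rest
#' volumes get independent noise. Condition-specific mean shifts implementing
#' the ground-truth percent signal change are placed 2 TRs late, matching the
#' hemodynamic shift the extraction step applies. WM/CSF nuisance channels
#' leak into ROI channels with coefficients `wmLeak`/`csfLeak`.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param subjectGraph symmetric logical ROI x ROI adjacency matrix.
#' @param subjectId identifier stored in the result.
#' @param seed seed; `NULL` (default) continues the RNG stream so cohorts can
#'   be generated in a loop under one seed.
#' @return A \linkS4class{RoiTimeSeries} with the ground-truth percent signal
#'   change in `@bscTruth`.
#' @export
simulateBoldSession <- function(config, subjectGraph, subjectId = "S0001",
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- config@blockDesign
  nvol <- length(design)
  if (nvol != 160L)
    stop("invalid config: block design must cover exactly 160 volumes")
  R <- config@roiCount
  if (!identical(dim(subjectGraph), as.integer(c(R, R))))
    stop("subjectGraph must be roiCount x roiCount")

  ## target correlation for task volumes: coupling on edges, identity elsewhere
  target <- diag(R)
  target[subjectGraph] <- config@coupling
  diag(target) <- 1
  ev <- eigen((target + t(target)) / 2, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    ## dense graphs make I + c*A indefinite; project onto the nearest
    ## correlation matrix (eigenvalue clip + unit-diagonal rescale)
    vals <- pmax(ev$values, 1e-8)
    m <- ev$vectors %*% (t(ev$vectors) * vals)
    m <- m / tcrossprod(sqrt(diag(m)))
    ev <- eigen((m + t(m)) / 2, symmetric = TRUE)
  }
  Lt <- t(ev$vectors %*% (t(ev$vectors) * sqrt(pmax(ev$values, 0))))

  task <- design != "rest"
  noise <- matrix(rnorm(nvol * R), nvol, R)
  noise[task, ] <- noise[task, , drop = FALSE] %*% Lt
  roi <- config@baseline + config@noiseSd * noise

  ## condition mean shifts, placed 2 TRs late (hemodynamic rise)
  shift <- 2L
  blockLen <- 8L
  for (cond in c("ambiguous", "angry")) {
    amp <- (if (cond == "ambiguous") config@bscAmbiguous else config@bscAngry)
    amp <- amp / 100 * config@baseline
    for (s in .blockStarts(design, cond)) {
      win <- (s + shift):(s + shift + blockLen - 1L)
      if (max(win) > nvol)
        stop("invalid config: shifted block runs off the end of the session")
      roi[win, ] <- roi[win, , drop = FALSE] +
        matrix(amp, length(win), R, byrow = TRUE)
    }
  }

  wm <- config@baseline + config@noiseSd * rnorm(nvol)
  csf <- config@baseline + config@noiseSd * rnorm(nvol)
  if (config@wmLeak != 0) roi <- roi + config@wmLeak * (wm - mean(wm))
  if (config@csfLeak != 0) roi <- roi + config@csfLeak * (csf - mean(csf))

  signal <- cbind(roi, WM = wm, CSF = csf)
  colnames(signal) <- c(config@roiNames, "WM", "CSF")
  new("RoiTimeSeries", subjectId = subjectId, signal = signal,
      design = design, trSeconds = config@trSeconds,
      bscTruth = list(ambiguous = setNames(config@bscAmbiguous, config@roiNames),
                      angry = setNames(config@bscAngry, config@roiNames)))
}

#' Simulate a cohort of BOLD sessions
#'
#' Draws one connectivity graph per subject from `pairConnectionProb`, then a
#' session per graph, all under a single seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param nSubjects cohort size (default from config).
#' @param seed seed (default: the config seed).
#' @return list with elements `sessions` (list of
#'   \linkS4class{RoiTimeSeries}) and `graphs` (the generating adjacencies).
#' @export
simulateBoldCohort <- function(config, nSubjects = config@nSubjects,
                               seed = config@seed) {
  set.seed(seed)
  graphs <- simulateSubjectGraphs(config, nSubjects, seed = NULL)
  sessions <- lapply(seq_len(nSubjects), function(s)
    simulateBoldSession(config, graphs[[s]],
                        subjectId = sprintf("S%04d", s), seed = NULL))
  list(sessions = sessions, graphs = graphs)
}

## ---------------------------------------------------------------------------
## Plain-text exchange for sessions and phenotypes
## ---------------------------------------------------------------------------

#' Write / read a BOLD session as TSV
#'
#' The signal matrix goes to `<prefix>.signal.tsv` (rows = volumes, columns =
#' named channels) and the design to `<prefix>.design.tsv` (volume index,
#' block label).
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param prefix file path prefix.
#' @return `writeBoldSession` returns the prefix invisibly; `readBoldSession`
#'   returns a \linkS4class{RoiTimeSeries}.
#' @export
writeBoldSession <- function(ts, prefix) {
  write.table(ts@signal, paste0(prefix, ".signal.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(volume = seq_along(ts@design), block = ts@design),
              paste0(prefix, ".design.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname writeBoldSession
#' @param subjectId identifier for the re-read session.
#' @param trSeconds repetition time to record.
#' @export
readBoldSession <- function(prefix, subjectId = basename(prefix),
                            trSeconds = 2.2) {
  sig <- as.matrix(read.table(paste0(prefix, ".signal.tsv"),
                              header = TRUE, sep = "\t", check.names = FALSE))
  des <- read.table(paste0(prefix, ".design.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  new("RoiTimeSeries", subjectId = subjectId, signal = sig,
      design = des$block, trSeconds = trSeconds, bscTruth = list())
}

#' Write / read a phenotype table as TSV
#'
#' Columns: `FID`, `IID`, `site`, `sex`, then one column per ROI.
#'
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @export
writePhenotypeTable <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypeTable
#' @export
readPhenotypeTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
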