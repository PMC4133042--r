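## From ROI time series and the block design to condition-specific
## functional-connectivity graphs, nodal degree, percent-signal-change
## phenotypes, and their population summaries.

#' Regress nuisance channels out of the ROI signals
#'
#' Each ROI channel is replaced by the residuals of an OLS fit on
#' [intercept, WM, CSF], with the channel mean added back so the signal
#' keeps its physical scale. A constant nuisance channel is dropped from
#' the model with a warning.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @return A \linkS4class{RoiTimeSeries} with cleaned ROI channels.
#' @export
regressNuisance <- function(ts) {
  sig <- ts@signal
  rois <- roiChannels(ts)
  nuis <- intersect(c("WM", "CSF"), colnames(sig))
  X <- matrix(1, nrow(sig), 1)
  for (ch in nuis) {
    if (sd(sig[, ch]) < 1e-12) {
      warning("constant nuisance channel ", ch, " dropped from the model")
    } else X <- cbind(X, sig[, ch])
  }
  qrX <- qr(X)
  for (r in rois) {
    mu <- mean(sig[, r])
    sig[, r] <- qr.resid(qrX, sig[, r]) + mu
  }
  out <- ts
  out@signal <- sig
  out
}

#' Extract the block-concatenated series for one condition
#'
#' For every block of the condition, takes the `blockLen` volumes starting
#' `shiftTr` volumes after block onset (the hemodynamic shift), mean-centers
#' the signal within each block, and concatenates the blocks. With the
#' standard design a face condition yields 5 x 8 = 40 volumes and the
#' control 9 x 8 = 72. A shifted window running off the end of the session
#' is an error, never a silent truncation.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param condition one of the design's block labels (not `rest`).
#' @param shiftTr hemodynamic shift in TRs (default 2).
#' @param blockLen block length in volumes (default 8).
#' @return numeric matrix (concatenated volumes x ROI channels).
#' @export
extractConditionSeries <- function(ts, condition, shiftTr = 2L,
                                   blockLen = 8L) {
  if (!condition %in% c("ambiguous", "angry", "control"))
    stop("unknown condition label: ", condition)
  starts <- .blockStarts(ts@design, condition)
  if (!length(starts)) stop("design contains no '", condition, "' blocks")
  nvol <- nrow(ts@signal)
  rois <- roiChannels(ts)
  pieces <- lapply(starts, function(s) {
    win <- (s + shiftTr):(s + shiftTr + blockLen - 1L)
    if (max(win) > nvol)
      stop("shifted block starting at volume ", s,
           " runs off the end of the session")
    x <- ts@signal[win, rois, drop = FALSE]
    sweep(x, 2, colMeans(x))
  })
  do.call(rbind, pieces)
}

#' Condition correlation matrix
#'
#' Pearson correlation between the concatenated series of every ROI pair.
#' The default realization of a face condition concatenates its face blocks
#' with the control blocks; pass `controlSeries = NULL` for a face-only
#' matrix.
#'
#' @param faceSeries matrix from [extractConditionSeries()] for the face
#'   condition.
#' @param controlSeries matching control-series matrix, or `NULL`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
conditionCorrelationMatrix <- function(faceSeries, controlSeries = NULL) {
  x <- if (is.null(controlSeries)) faceSeries else rbind(faceSeries,
                                                         controlSeries)
  r <- cor(x)
  (r + t(r)) / 2
}

#' Threshold a correlation matrix and count nodal degree
#'
#' Edges are pairs with correlation strictly above `rMin` (negative
#' correlations never create edges); degree is the per-ROI edge count.
#'
#' @param corr symmetric correlation matrix.
#' @param rMin edge threshold (default 0.3, strict inequality).
#' @param condition label stored in the graph.
#' @return A \linkS4class{ConnectivityGraph}.
#' @export
thresholdAndDegree <- function(corr, rMin = 0.3, condition = "ambiguous") {
  adj <- corr > rMin
  diag(adj) <- FALSE
  adj <- adj & t(adj)
  new("ConnectivityGraph", condition = condition, corr = corr,
      adjacency = adj, degree = as.integer(rowSums(adj)), threshold = rMin)
}

#' Build the connectivity graph for one subject and condition
#'
#' Convenience wrapper: nuisance regression, condition and control series
#' extraction, correlation, threshold, degree.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param condition `"ambiguous"` or `"angry"`.
#' @param rMin edge threshold (default 0.3).
#' @param includeControl concatenate the control blocks into the condition
#'   series (default `TRUE`).
#' @param cleanNuisance run [regressNuisance()] first (default `TRUE`).
#' @inheritParams extractConditionSeries
#' @return A \linkS4class{ConnectivityGraph}.
#' @export
buildConnectivityGraph <- function(ts, condition = "ambiguous", rMin = 0.3,
                                   includeControl = TRUE,
                                   cleanNuisance = TRUE,
                                   shiftTr = 2L, blockLen = 8L) {
  if (cleanNuisance) ts <- regressNuisance(ts)
  face <- extractConditionSeries(ts, condition, shiftTr, blockLen)
  ctrl <- if (includeControl)
    extractConditionSeries(ts, "control", shiftTr, blockLen) else NULL
  thresholdAndDegree(conditionCorrelationMatrix(face, ctrl), rMin, condition)
}

#' Percent BOLD signal change per ROI
#'
#' Transparent block-mean contrast standing in for a full GLM extraction:
#' 100 * (mean shifted-condition signal - mean shifted-control signal) /
#' mean whole-run signal, per ROI.
#'
#' @inheritParams extractConditionSeries
#' @return named numeric vector, one value per ROI.
#' @export
percentBSC <- function(ts, condition, shiftTr = 2L, blockLen = 8L) {
  if (!condition %in% c("ambiguous", "angry"))
    stop("condition must be a face condition (ambiguous/angry)")
  rois <- roiChannels(ts)
  nvol <- nrow(ts@signal)
  winMean <- function(cond) {
    starts <- .blockStarts(ts@design, cond)
    if (!length(starts)) stop("design contains no '", cond, "' blocks")
    wins <- unlist(lapply(starts, function(s) {
      win <- (s + shiftTr):(s + shiftTr + blockLen - 1L)
      if (max(win) > nvol)
        stop("shifted block starting at volume ", s,
             " runs off the end of the session")
      win
    }))
    colMeans(ts@signal[wins, rois, drop = FALSE])
  }
  runMean <- colMeans(ts@signal[, rois, drop = FALSE])
  100 * (winMean(condition) - winMean("control")) / runMean
}

#' Per-site z-scoring of phenotype columns
#'
#' Standardizes every ROI column to mean 0, SD 1 within each acquisition
#' site, removing additive scanner/site offsets. The `sex` column is kept
#' untouched as a covariate.
#'
#' @param pheno data.frame with `site` plus ROI columns (and optionally
#'   `FID`, `IID`, `sex`).
#' @return the table with standardized ROI columns.
#' @export
standardizePhenotypes <- function(pheno) {
  if (!"site" %in% names(pheno)) stop("phenotype table needs a 'site' column")
  cols <- setdiff(names(pheno)[vapply(pheno, is.numeric, logical(1))],
                  c("site", "sex"))
  for (s in unique(pheno$site)) {
    rows <- pheno$site == s
    for (cl in cols) {
      x <- pheno[rows, cl]
      pheno[rows, cl] <- (x - mean(x)) / sd(x)
    }
  }
  pheno
}

.degreeMatrix <- function(graphs) {
  rows <- lapply(graphs, function(g)
    if (is(g, "ConnectivityGraph")) as.numeric(g@degree) else as.numeric(g))
  degs <- do.call(rbind, rows)
  if (is(graphs[[1]], "ConnectivityGraph"))
    colnames(degs) <- rownames(graphs[[1]]@corr)
  degs
}

#' Population mean and SD of nodal degree
#'
#' @param graphs list of per-subject \linkS4class{ConnectivityGraph}s (or
#'   plain degree vectors).
#' @return data.frame with columns `roi`, `mean`, `sd`.
#' @export
degreePopulationStats <- function(graphs) {
  degs <- .degreeMatrix(graphs)
  data.frame(roi = colnames(degs) %||% sprintf("ROI%02d", seq_len(ncol(degs))),
             mean = colMeans(degs),
             sd = apply(degs, 2, sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Proportion of subjects connected, per ROI pair
#'
#' Fraction of subjects whose graph contains each edge; the diagonal is 1 by
#' convention.
#'
#' @param graphs list of per-subject \linkS4class{ConnectivityGraph}s.
#' @return symmetric numeric matrix with entries in [0, 1].
#' @export
connectionProportions <- function(graphs) {
  adj <- lapply(graphs, function(g)
    if (is(g, "ConnectivityGraph")) g@adjacency * 1 else g * 1)
  prop <- Reduce(`+`, adj) / length(adj)
  diag(prop) <- 1
  prop
}
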