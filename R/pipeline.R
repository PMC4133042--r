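## Configuration-driven orchestration: simulate -> QC -> GRM -> REML ->
## connectivity -> second-level inference, emitting the study-analog tables.

#' Pipeline configuration
#'
#' Flat named list of every pipeline knob. Thresholds default to the values
#' the emulated study used (missingness 5%, HWE p <= 1e-4, MAF < 0.01, call
#' rate 97%, relatedness cutoff 0.05, 10 PCs, edge threshold r > 0.3,
#' alpha = 0.05, 50,000 count-null realizations). Cohort sizes default to a
#' demo scale that completes in minutes.
#'
#' @param nSubjects,nSnps,nCausal,targetH2 synthetic cohort parameters
#'   (demo defaults 300 / 2000 / 200 / 0.5).
#' @param missMax,hwePMin,mafMin,callRateMin,relCutoff,nPCs genotype QC and
#'   GRM settings.
#' @param rMin,alpha,nRealizations connectivity and count-test settings.
#' @param condition face condition to analyse.
#' @param genetics,connectivity stage toggles.
#' @param seed global seed.
#' @return named list with class `pipelineConfig`.
#' @export
pipelineConfig <- function(nSubjects = 300, nSnps = 2000, nCausal = 200,
                           targetH2 = 0.5,
                           missMax = 0.05, hwePMin = 1e-4, mafMin = 0.01,
                           callRateMin = 0.97, relCutoff = 0.05, nPCs = 10,
                           rMin = 0.3, alpha = 0.05, nRealizations = 50000,
                           condition = "ambiguous",
                           genetics = TRUE, connectivity = TRUE,
                           seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipelineConfig"
  cfg
}

.configHash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

.writeStamped <- function(df, path, stamp) {
  con <- file(path, "w")
  writeLines(stamp, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Run the full pipeline
#'
#' Simulates the cohort, runs genotype QC, GRM construction, relatedness
#' pruning and PCA, fits univariate GREML with the boundary-mixture LRT per
#' ROI, builds per-subject connectivity graphs and degree statistics, runs
#' the Monte-Carlo count test and the trend fits, classifies the
#' Optional/Obligatory subnetworks, and fits bivariate GREML across the
#' subnetwork ROIs. Every table is written as TSV under `outDir` with a
#' header line recording the config hash and seed; the count test is written
#' as JSON. Stage failures abort with the stage name.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory results.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# neuroGREML %s | config %s | seed %d",
                   as.character(packageVersion("neuroGREML")),
                   .configHash(config), config$seed)
  logf <- file.path(outDir, "pipeline.log")
  logit <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  t0 <- Sys.time()
  logit("start %s", format(t0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  res <- list(config = config)

  sim <- simConfig(nSubjects = config$nSubjects, nSnps = config$nSnps,
                   nCausal = config$nCausal, targetH2 = config$targetH2,
                   seed = config$seed)

  ## -- connectivity branch -------------------------------------------------
  if (config$connectivity) {
    cohort <- stage("bold", simulateBoldCohort(sim))
    graphs <- stage("connectivity", lapply(cohort$sessions, function(ts)
      buildConnectivityGraph(ts, config$condition, rMin = config$rMin)))
    stats <- degreePopulationStats(graphs)
    bsc <- t(vapply(cohort$sessions, function(ts)
      percentBSC(ts, config$condition), numeric(sim@roiCount)))
    table1 <- data.frame(roi = stats$roi,
                         bsc_mean = colMeans(bsc),
                         bsc_sd = apply(bsc, 2, sd),
                         degree_mean = stats$mean, degree_sd = stats$sd)
    .writeStamped(table1, file.path(outDir, "table1_degree_bsc.tsv"), stamp)
    prop <- connectionProportions(graphs)
    .writeStamped(data.frame(roi = rownames(prop), round(prop, 4),
                             check.names = FALSE),
                  file.path(outDir, "table2_connection_proportions.tsv"), stamp)
    subnet <- classifySubnetworks(stats)
    .writeStamped(data.frame(roi = names(subnet@labels),
                             label = unname(subnet@labels)),
                  file.path(outDir, "subnetworks.tsv"), stamp)
    res$degreeStats <- stats
    res$proportions <- prop
    res$subnetworks <- subnet
    res$bsc <- bsc
    logit("connectivity done: %d subjects", length(graphs))
  }

  ## -- genetics branch -----------------------------------------------------
  if (config$genetics) {
    g <- stage("simulate", simulateGenotypes(sim))
    pheno <- stage("phenotypes", simulateMultiRoiPhenotypes(g, sim, seed = NULL))
    qcS <- stage("qc", snpQC(g, config$missMax, config$hwePMin, config$mafMin))
    qcI <- stage("qc", sampleQC(qcS$genotypes, config$callRateMin))
    gq <- qcI$genotypes
    pheno <- pheno[match(sampleIds(gq)$IID, pheno$IID), ]
    grm <- stage("grm", computeGRM(gq))
    pruned <- stage("prune", pruneRelated(grm, config$relCutoff))
    keep <- pruned$keep
    grmK <- new("GRM", values = grmValues(grm)[keep, keep],
                nsnp = grmNsnp(grm)[keep, keep, drop = FALSE],
                sampleIds = sampleIds(grm)[keep, , drop = FALSE])
    pheno <- pheno[keep, , drop = FALSE]
    pcs <- stage("pca", grmPCA(grmK, k = min(config$nPCs, nrow(pheno) - 1L)))
    phenoZ <- standardizePhenotypes(pheno)
    rois <- sim@roiNames
    X <- cbind(1, sex = phenoZ$sex == 1, pcs)

    fits <- stage("reml", lapply(rois, function(r) {
      y <- phenoZ[[r]]
      fit <- remlUnivariate(y, X, grmK)
      lrt <- lrtVg(fit, remlNull(y, X)$logL)
      list(fit = fit, lrt = lrt)
    }))
    tabS1 <- data.frame(
      roi = rois,
      VG = vapply(fits, function(f) f$fit@VG, 1),
      VE = vapply(fits, function(f) f$fit@VE, 1),
      Vp = vapply(fits, function(f) f$fit@Vp, 1),
      ratio = vapply(fits, function(f) f$fit@ratio, 1),
      se = vapply(fits, function(f) f$fit@seRatio, 1),
      logL = vapply(fits, function(f) f$fit@logL, 1),
      lrt = vapply(fits, function(f) f$lrt@statistic, 1),
      p = vapply(fits, function(f) f$lrt@pValue, 1))
    .writeStamped(tabS1, file.path(outDir, "tableS1_greml.tsv"), stamp)
    res$greml <- tabS1
    logit("greml done: %d ROIs, %d samples", length(rois), nrow(phenoZ))

    ## count statistic with its correlated null
    phenoCorr <- cor(as.matrix(phenoZ[, rois]))
    observed <- sum(tabS1$p < config$alpha)
    cnt <- stage("count", mcCountPvalue(
      phenoCorr, observed, alpha = config$alpha,
      nRealizations = config$nRealizations, seed = config$seed))
    jsonlite::write_json(
      list(observed = observed, p = cnt@pValue, alpha = cnt@alpha,
           expected_false_positives =
             expectedFalsePositives(length(rois), config$alpha),
           histogram = as.list(cnt@histogram),
           config = .configHash(config), seed = config$seed),
      file.path(outDir, "count_test.json"), auto_unbox = TRUE, digits = NA)
    res$countTest <- cnt

    if (config$connectivity) {
      tr <- list(
        h2_vs_degree_sd = fitLinearTrend(res$degreeStats$sd, tabS1$ratio),
        degree_sd_vs_mean = fitQuadraticTrend(res$degreeStats$mean,
                                              res$degreeStats$sd),
        bsc_vs_degree_sd = fitQuadraticTrend(colMeans(res$bsc),
                                             res$degreeStats$sd))
      trendTab <- data.frame(
        relation = names(tr),
        r2 = vapply(tr, function(x) x@r2, 1),
        f = vapply(tr, function(x) x@fstat, 1),
        df1 = vapply(tr, function(x) x@df1, 1),
        df2 = vapply(tr, function(x) x@df2, 1),
        p = vapply(tr, function(x) x@pValue, 1))
      .writeStamped(trendTab, file.path(outDir, "fig3_trends.tsv"), stamp)
      res$trends <- tr

      ## bivariate rG across the subnetwork ROIs (Table S4 analog)
      members <- names(res$subnetworks@labels)[
        res$subnetworks@labels != "Neither"]
      if (length(members) >= 2) {
        pairs <- utils::combn(members, 2)
        biv <- stage("reml-bivar", apply(pairs, 2, function(pr) {
          b <- remlBivariate(phenoZ[[pr[1]]], phenoZ[[pr[2]]], X, grmK)
          data.frame(roi1 = pr[1], roi2 = pr[2], rG = b@rG, se = b@seRG,
                     covG = b@covG, p = b@pCovG, unstable = b@unstable)
        }))
        biv <- do.call(rbind, biv)
        .writeStamped(biv, file.path(outDir, "tableS4_bivariate.tsv"), stamp)
        res$bivariate <- biv
      }
    }

    ## GWAS ladder per ROI (Fig 2 analog), first ROI only at demo scale
    gw <- stage("gwas", gwasScan(gq[, keep], phenoZ[[rois[1]]],
                                 covariates = cbind(sex = phenoZ$sex == 1, pcs)))
    counts <- snpCountByThreshold(gw)
    .writeStamped(data.frame(threshold = names(counts), count = counts),
                  file.path(outDir, "fig2_snp_counts.tsv"), stamp)
    res$gwasCounts <- counts

    split <- randomSplitHalfR2(phenoZ, seed = config$seed)
    .writeStamped(data.frame(r2 = split$r2, nA = split$nA, nB = split$nB),
                  file.path(outDir, "figS3_split_half.tsv"), stamp)
    res$splitHalf <- split
  }

  logit("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(res)
}
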