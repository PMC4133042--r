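## Genotype quality control: per-SNP filters (missingness, Hardy-Weinberg
## exact test, minor allele frequency, applied in that order) and the
## per-sample call-rate filter.

.qcReport <- function(removed, nInput, thresholds, unit) {
  new("QcReport", removed = removed, nInput = as.integer(nInput),
      nRetained = as.integer(nInput - sum(removed)),
      thresholds = thresholds, unit = unit)
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test by full enumeration of heterozygote counts
#' conditional on the observed allele counts. The p-value sums the
#' probabilities of all outcomes no more probable than the observed one.
#'
#' @param nAA,nAa,naa genotype counts (major hom, het, minor hom; the
#'   labelling is symmetric).
#' @return p-value in (0, 1].
#' @examples
#' hweExactTest(57, 14, 50)   # strong heterozygote deficit, tiny p
#' hweExactTest(25, 50, 25)   # mode of the conditional distribution, p = 1
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("genotype counts must be non-negative")
  n <- nAA + nAa + naa
  if (n < 1) stop("at least one genotype is required")
  n1 <- min(2L * nAA + nAa, 2L * naa + nAa)   # rare-allele count
  hs <- seq.int(n1 %% 2L, n1, by = 2L)
  ## conditional distribution of the het count given n and the allele count:
  ## P(h) proportional to 2^h * n! / (homRare! h! homCommon!)
  lp <- hs * log(2) + lfactorial(n) -
    lfactorial((n1 - hs) / 2) - lfactorial(hs) -
    lfactorial(n - hs - (n1 - hs) / 2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  pObs <- pr[match(nAa, hs)]
  if (is.na(pObs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

.checkFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || x < 0 || x > 1)
    stop("invalid config: ", name, " must be a single value in [0, 1]")
}

#' Per-SNP quality control
#'
#' Applies, in order: missingness (> `missMax` removed), Hardy-Weinberg exact
#' test (p <= `hwePMin` removed), and minor allele frequency (< `mafMin`
#' removed, which also catches monomorphic SNPs). Counts are order-dependent
#' and recorded per filter in the report.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param missMax maximum tolerated missing fraction (default 0.05).
#' @param hwePMin HWE exact-test exclusion threshold (default 1e-4; SNPs at
#'   or below it are removed).
#' @param mafMin minimum minor allele frequency (default 0.01, strict).
#' @return list with elements `genotypes` (filtered
#'   \linkS4class{GenotypeData}) and `report` (\linkS4class{QcReport}).
#' @export
snpQC <- function(g, missMax = 0.05, hwePMin = 1e-4, mafMin = 0.01) {
  .checkFraction(missMax, "missMax")
  .checkFraction(hwePMin, "hwePMin")
  .checkFraction(mafMin, "mafMin")
  d <- dosages(g)
  if (!nrow(d)) stop("empty genotype matrix")
  m0 <- nrow(d)
  keep <- rep(TRUE, m0)

  missFrac <- rowMeans(is.na(d))
  dropMiss <- missFrac > missMax
  keep[dropMiss] <- FALSE

  dropHwe <- rep(FALSE, m0)
  for (i in which(keep)) {
    di <- d[i, ]
    n2 <- sum(di == 2, na.rm = TRUE)
    n1 <- sum(di == 1, na.rm = TRUE)
    n0 <- sum(di == 0, na.rm = TRUE)
    if (n0 + n1 + n2 == 0) next       # all-missing survives to MAF as NaN? guard
    dropHwe[i] <- hweExactTest(n0, n1, n2) <= hwePMin
  }
  keep[dropHwe] <- FALSE

  freq <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  dropMaf <- keep & (is.nan(maf) | maf < mafMin)
  keep[dropMaf] <- FALSE

  removed <- c(missingness = sum(dropMiss), hwe = sum(dropHwe),
               maf = sum(dropMaf))
  out <- g[keep, ]
  list(genotypes = as(out, "GenotypeData"),
       report = .qcReport(as.integer(removed) |>
                            setNames(names(removed)), m0,
                          list(missMax = missMax, hwePMin = hwePMin,
                               mafMin = mafMin), "SNPs"))
}

#' Per-sample quality control
#'
#' Removes samples whose genotyping call rate is strictly below
#' `callRateMin`; a sample at exactly the threshold is retained.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param callRateMin minimum call rate (default 0.97).
#' @return list with `genotypes` and `report`, as [snpQC()].
#' @export
sampleQC <- function(g, callRateMin = 0.97) {
  .checkFraction(callRateMin, "callRateMin")
  d <- dosages(g)
  n0 <- ncol(d)
  callRate <- colMeans(!is.na(d))
  keep <- callRate >= callRateMin
  out <- g[, keep]
  list(genotypes = as(out, "GenotypeData"),
       report = .qcReport(c(callRate = sum(!keep)), n0,
                          list(callRateMin = callRateMin), "samples"))
}
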