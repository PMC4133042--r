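## Per-SNP ordinary least squares association scan (the plain fixed-effect
## GWAS the study ran on standardized phenotypes), plus the count of SNPs
## passing nominal significance thresholds.

#' Per-SNP association scan
#'
#' Ordinary least squares of the phenotype on each SNP's dosage plus shared
#' covariates (sex, ancestry PCs, ...), with two-sided t-test p-values.
#' Covariates are projected out once (Frisch-Waugh), so the scan is a single
#' matrix product. Missing dosages are mean-imputed per SNP. Monomorphic
#' SNPs get effect 0, p = 1 and a flag.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param y phenotype vector.
#' @param covariates covariate matrix (an intercept is always included), or
#'   `NULL`.
#' @return data.frame with columns `snp`, `beta`, `se`, `t`, `p`, `flagged`.
#' @export
gwasScan <- function(g, y, covariates = NULL) {
  d <- dosages(g)
  n <- ncol(d)
  if (length(y) != n) stop("phenotype length must match sample count")
  X <- cbind(intercept = rep(1, n), covariates)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  p <- ncol(X)

  qrX <- qr(X)
  yr <- qr.resid(qrX, y)

  ## mean-impute missing dosages, then residualize all SNPs at once
  G <- t(d)
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  Gr <- qr.resid(qrX, G)

  gg <- colSums(Gr^2)
  gy <- drop(crossprod(Gr, yr))
  mono <- gg < 1e-12
  beta <- ifelse(mono, 0, gy / pmax(gg, 1e-300))
  df <- n - p - 1
  rss <- sum(yr^2) - beta^2 * gg
  sigma2 <- pmax(rss, 0) / df
  se <- ifelse(mono, NA_real_, sqrt(sigma2 / pmax(gg, 1e-300)))
  tval <- ifelse(mono, 0, beta / se)
  pval <- ifelse(mono, 1, 2 * pt(-abs(tval), df))

  data.frame(snp = snpMeta(g)$id, beta = beta, se = se, t = tval,
             p = pval, flagged = mono, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Count SNPs below nominal p-value thresholds
#'
#' Counts of scan p-values strictly below each threshold; across ROIs these
#' counts trend with the VG/Vp estimates.
#'
#' @param gwas data.frame from [gwasScan()].
#' @param thresholds numeric thresholds (default the nominal ladder
#'   0.001 ... 0.3).
#' @return named integer vector of counts, one per threshold.
#' @export
snpCountByThreshold <- function(gwas,
                                thresholds = c(0.001, 0.01, 0.05, 0.1,
                                               0.15, 0.2, 0.25, 0.3)) {
  vapply(thresholds, function(t) sum(gwas$p < t), integer(1)) |>
    setNames(as.character(thresholds))
}
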