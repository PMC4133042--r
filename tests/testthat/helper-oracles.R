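## Independent oracles used across the suite. Each takes a route different
## from the package implementation: closed-form factorial identities, dense
## matrix algebra, or exhaustive double loops.

## Exact conditional distribution of the heterozygote count given the allele
## count, via the closed-form hypergeometric-type identity
##   P(h) = n! / (hr! h! hc!) * 2^h * nRare! nCommon! / (2n)!
hweOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nRare <- min(2 * nAA + nAa, 2 * naa + nAa)
  nCommon <- 2 * n - nRare
  hs <- seq(nRare %% 2, nRare, by = 2)
  pr <- vapply(hs, function(h) {
    hr <- (nRare - h) / 2
    hc <- n - h - hr
    exp(lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
          h * log(2) + lfactorial(nRare) + lfactorial(nCommon) -
          lfactorial(2 * n))
  }, numeric(1))
  pObs <- pr[match(nAa, hs)]
  sum(pr[pr <= pObs * (1 + 1e-12)])
}

## Restricted log-likelihood by dense matrix algebra (no eigen rotation):
## logL = -1/2 (log|V| + log|X'V^-1 X| + y'Py) - (n-p)/2 log(2 pi)
remlLogLikDense <- function(y, X, A, vg, ve) {
  n <- length(y)
  V <- vg * A + ve * diag(n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  -0.5 * (logdetV + determinant(XtViX)$modulus[1] + drop(t(y) %*% P %*% y)) -
    0.5 * (n - ncol(X)) * log(2 * pi)
}

## 2-D grid search of the restricted likelihood, grid step `step * Vp`
remlGridOracle <- function(y, X, A, step = 0.01, upper = 1.2) {
  vp <- var(y)
  grid <- seq(step * vp, upper * vp, by = step * vp)
  best <- c(vg = NA, ve = NA, logL = -Inf)
  for (vg in grid) for (ve in grid) {
    ll <- remlLogLikDense(y, X, A, vg, ve)
    if (ll > best["logL"]) best <- c(vg = vg, ve = ve, logL = ll)
  }
  best
}

## nodal degree by an explicit double loop with strict inequality
degreeBruteForce <- function(corr, rMin = 0.3) {
  k <- nrow(corr)
  deg <- integer(k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && corr[i, j] > rMin) deg[i] <- deg[i] + 1L
  }
  deg
}

## small HWE genotype panel with controllable quirks
makeToyGenotypes <- function(dosage, p = NULL) {
  m <- nrow(dosage); n <- ncol(dosage)
  meta <- data.frame(id = sprintf("s%d", seq_len(m)), chrom = 1L,
                     pos = seq_len(m), a1 = "A", a2 = "G",
                     stringsAsFactors = FALSE)
  if (!is.null(p)) meta$p <- p
  ids <- data.frame(FID = sprintf("F%d", seq_len(n)),
                    IID = sprintf("I%d", seq_len(n)),
                    stringsAsFactors = FALSE)
  GenotypeData(dosage, meta, ids)
}

grmFromMatrix <- function(a, nsnp = 100L) {
  n <- nrow(a)
  new("GRM", values = a, nsnp = matrix(nsnp, n, n),
      sampleIds = data.frame(FID = sprintf("F%d", seq_len(n)),
                             IID = sprintf("I%d", seq_len(n)),
                             stringsAsFactors = FALSE))
}
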