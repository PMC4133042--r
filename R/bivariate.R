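## Bivariate AI-REML over one GRM and six (co)variance components
##   theta = (VG1, VG2, covG, VE1, VE2, covE).
## After rotating both traits by the GRM eigenvectors, V is block-diagonal
## with one 2x2 block per eigenvalue, so all P-operations are vectorized
## over samples.

## Per-block 2x2 inverse of V; v components are n-vectors.
.bivVinv <- function(d, th) {
  v11 <- th[1] * d + th[4]
  v22 <- th[2] * d + th[5]
  v12 <- th[3] * d + th[6]
  det <- v11 * v22 - v12^2
  if (any(det <= 0) || any(v11 <= 0) || any(v22 <= 0)) return(NULL)
  list(i11 = v22 / det, i12 = -v12 / det, i22 = v11 / det, logdet = sum(log(det)))
}

## apply the block-diagonal V^-1 to an n x 2 matrix
.bivViw <- function(vi, w) {
  cbind(vi$i11 * w[, 1] + vi$i12 * w[, 2],
        vi$i12 * w[, 1] + vi$i22 * w[, 2])
}

## X'V^-1X (2p x 2p), X'V^-1w, and a P-operator for the stacked model
.bivProj <- function(vi, Xs) {
  b11 <- crossprod(Xs, Xs * vi$i11)
  b12 <- crossprod(Xs, Xs * vi$i12)
  b22 <- crossprod(Xs, Xs * vi$i22)
  C <- rbind(cbind(b11, b12), cbind(b12, b22))
  Cinv <- solve(C)
  p <- ncol(Xs)
  Pfun <- function(w) {                 # w is n x 2
    viw <- .bivViw(vi, w)
    rhs <- c(crossprod(Xs, viw[, 1]), crossprod(Xs, viw[, 2]))
    beta <- Cinv %*% rhs
    xb <- cbind(Xs %*% beta[seq_len(p)], Xs %*% beta[p + seq_len(p)])
    viw - .bivViw(vi, xb)
  }
  list(C = C, Cinv = Cinv, Pfun = Pfun)
}

## the six rotated derivative matrices applied to an n x 2 matrix
.bivAw <- function(k, d, w) {
  switch(k,
         cbind(d * w[, 1], 0),            # VG1
         cbind(0, d * w[, 2]),            # VG2
         cbind(d * w[, 2], d * w[, 1]),   # covG
         cbind(w[, 1], 0),                # VE1
         cbind(0, w[, 2]),                # VE2
         cbind(w[, 2], w[, 1]))           # covE
}

## tr(P A_k) for all six components
.bivTrPA <- function(vi, Xs, Cinv, d) {
  one <- rep(1, length(d))
  trV <- c(sum(d * vi$i11), sum(d * vi$i22), 2 * sum(d * vi$i12),
           sum(vi$i11), sum(vi$i22), 2 * sum(vi$i12))
  ## G = V^-1 A_k V^-1 per block; for A = [[m,0],[0,0]]:
  g1 <- function(m) list(g11 = m * vi$i11^2, g12 = m * vi$i11 * vi$i12,
                         g22 = m * vi$i12^2)
  g2 <- function(m) list(g11 = m * vi$i12^2, g12 = m * vi$i12 * vi$i22,
                         g22 = m * vi$i22^2)
  gc <- function(m) list(g11 = 2 * m * vi$i11 * vi$i12,
                         g12 = m * (vi$i11 * vi$i22 + vi$i12^2),
                         g22 = 2 * m * vi$i12 * vi$i22)
  gs <- list(g1(d), g2(d), gc(d), g1(one), g2(one), gc(one))
  vapply(seq_len(6), function(k) {
    g <- gs[[k]]
    m11 <- crossprod(Xs, Xs * g$g11)
    m12 <- crossprod(Xs, Xs * g$g12)
    m22 <- crossprod(Xs, Xs * g$g22)
    M <- rbind(cbind(m11, m12), cbind(m12, m22))
    trV[k] - sum(diag(Cinv %*% M))
  }, numeric(1))
}

.bivLogLik <- function(Y, Xs, d, th) {
  vi <- .bivVinv(d, th)
  if (is.null(vi)) return(-Inf)
  pr <- tryCatch(.bivProj(vi, Xs), error = function(e) NULL)
  if (is.null(pr)) return(-Inf)
  PY <- pr$Pfun(Y)
  yPy <- sum(Y * PY)
  n2 <- 2 * nrow(Y); p2 <- 2 * ncol(Xs)
  ldC <- determinant(pr$C)$modulus[1]
  -0.5 * (vi$logdet + ldC + yPy) - 0.5 * (n2 - p2) * log(2 * pi)
}

## keep the covariances inside the PD cone
.bivClamp <- function(th, floorV, rhoMax = 0.9999) {
  th[c(1, 2, 4, 5)] <- pmax(th[c(1, 2, 4, 5)], floorV)
  bG <- rhoMax * sqrt(th[1] * th[2])
  bE <- rhoMax * sqrt(th[4] * th[5])
  th[3] <- min(max(th[3], -bG), bG)
  th[6] <- min(max(th[6], -bE), bE)
  th
}

#' Bivariate GREML: genetic covariance and correlation of two traits
#'
#' AI-REML over six components (VG1, VG2, covG, VE1, VE2, covE) for two
#' traits sharing one GRM, initialized from the univariate fits. Reports the
#' genetic correlation rG = covG / sqrt(VG1*VG2) with a delta-method SE and a
#' Wald p-value for covG = 0. Samples missing either trait are dropped
#' (pairwise-complete re-alignment). When either genetic variance sits at
#' its boundary the result is flagged unstable (rG is then ill-defined).
#'
#' @param y1,y2 phenotype vectors on the same samples as `grm`.
#' @param X covariate matrix (intercept added if `NULL`), shared by both
#'   traits.
#' @param grm a \linkS4class{GRM}.
#' @param maxIter,tol iteration cap and relative logL tolerance.
#' @return A \linkS4class{BivariateComponents}.
#' @export
remlBivariate <- function(y1, y2, X = NULL, grm, maxIter = 100L, tol = 1e-8) {
  a <- grmValues(grm)
  n0 <- length(y1)
  if (length(y2) != n0 || nrow(a) != n0)
    stop("trait and GRM dimensions differ")
  if (is.null(X)) X <- matrix(1, n0, 1)
  X <- as.matrix(X)
  ok <- !is.na(y1) & !is.na(y2) & !rowSums(is.na(X))
  y1 <- y1[ok]; y2 <- y2[ok]
  X <- X[ok, , drop = FALSE]
  a <- a[ok, ok, drop = FALSE]
  n <- length(y1)

  ed <- eigen(a, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  U <- ed$vectors
  Y <- cbind(drop(crossprod(U, y1)), drop(crossprod(U, y2)))
  Xs <- crossprod(U, X)

  subGrm <- new("GRM", values = a, nsnp = matrix(1L, n, n),
                sampleIds = data.frame(FID = as.character(seq_len(n)),
                                       IID = as.character(seq_len(n))))
  f1 <- remlUnivariate(y1, X, subGrm)
  f2 <- remlUnivariate(y2, X, subGrm)

  r1 <- lm.fit(X, y1)$residuals
  r2 <- lm.fit(X, y2)$residuals
  covP <- cov(r1, r2)
  hbar <- (f1@ratio + f2@ratio) / 2
  vp <- sqrt(var(y1) * var(y2))
  floorV <- 1e-6 * vp
  th <- .bivClamp(c(f1@VG, f2@VG, covP * hbar,
                    f1@VE, f2@VE, covP * (1 - hbar)), floorV)

  logL <- .bivLogLik(Y, Xs, d, th)
  converged <- FALSE
  iter <- 0L
  AI <- NULL

  for (it in seq_len(maxIter)) {
    iter <- it
    vi <- .bivVinv(d, th)
    pr <- .bivProj(vi, Xs)
    PY <- pr$Pfun(Y)
    yPAPy <- vapply(seq_len(6), function(k) sum(PY * .bivAw(k, d, PY)),
                    numeric(1))
    trPA <- .bivTrPA(vi, Xs, pr$Cinv, d)
    score <- 0.5 * (yPAPy - trPA)

    Tk <- lapply(seq_len(6), function(k) .bivAw(k, d, PY))
    PTk <- lapply(Tk, pr$Pfun)
    AI <- matrix(0, 6, 6)
    for (j in seq_len(6)) for (k in j:6) {
      AI[j, k] <- AI[k, j] <- 0.5 * sum(Tk[[j]] * PTk[[k]])
    }

    delta <- tryCatch(solve(AI, score), error = function(e) score * 1e-3)
    if (it == 1L) delta <- delta * 0.5       # cautious first move
    newTh <- .bivClamp(th + delta, floorV)
    newLogL <- .bivLogLik(Y, Xs, d, newTh)
    half <- 0L
    while ((!is.finite(newLogL) || newLogL < logL - 1e-8) && half < 30L) {
      delta <- delta / 2
      newTh <- .bivClamp(th + delta, floorV)
      newLogL <- .bivLogLik(Y, Xs, d, newTh)
      half <- half + 1L
    }
    if (!is.finite(newLogL)) break
    done <- abs(newLogL - logL) < tol * (abs(logL) + 1)
    th <- newTh
    logL <- newLogL
    if (done && it > 1L) { converged <- TRUE; break }
  }

  AIinv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 6, 6))
  vg1 <- th[1]; vg2 <- th[2]; cg <- th[3]
  rg <- cg / sqrt(vg1 * vg2)
  gradRg <- c(-rg / (2 * vg1), -rg / (2 * vg2), 1 / sqrt(vg1 * vg2),
              0, 0, 0)
  varRg <- drop(gradRg %*% AIinv %*% gradRg)
  seRg <- if (is.finite(varRg)) sqrt(max(0, varRg)) else NA_real_
  seCg <- if (is.finite(AIinv[3, 3])) sqrt(max(0, AIinv[3, 3])) else NA_real_
  pCg <- if (is.finite(seCg) && seCg > 0) 2 * pnorm(-abs(cg) / seCg)
         else NA_real_
  unstable <- vg1 <= 1.5 * floorV || vg2 <= 1.5 * floorV

  new("BivariateComponents",
      VG1 = vg1, VG2 = vg2, covG = cg,
      VE1 = th[4], VE2 = th[5], covE = th[6],
      rG = rg, seRG = seRg, pCovG = pCg,
      logL = logL, nIter = iter,
      converged = converged, unstable = unstable)
}
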