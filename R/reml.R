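## Average-information REML for the single-GRM animal model
##   y = Xb + g + e,  var(g) = A*VG,  var(e) = I*VE.
## The GRM is eigendecomposed once (A = U D U'); in the rotated basis V is
## diagonal, so every iteration is O(n p^2). One EM warm-up step precedes the
## AI updates, following common GREML practice.

## Restricted log-likelihood at (vg, ve) in the rotated basis.
## Returns -Inf when V is not positive definite.
.remlLogLik <- function(ystar, Xstar, d, vg, ve) {
  v <- vg * d + ve
  if (any(v <= 0)) return(-Inf)
  XtVi <- Xstar / v
  XtViX <- crossprod(Xstar, XtVi)
  ch <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(XtVi, ystar)))
  Py <- ystar / v - XtVi %*% beta
  yPy <- sum(ystar * Py)
  n <- length(ystar); p <- ncol(Xstar)
  -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + yPy) -
    0.5 * (n - p) * log(2 * pi)
}

## P applied to a vector, plus the quantities AI-REML needs.
.remlParts <- function(ystar, Xstar, d, vg, ve) {
  v <- vg * d + ve
  XtVi <- Xstar / v
  XtViX <- crossprod(Xstar, XtVi)
  XtViXinv <- solve(XtViX)
  Pfun <- function(w) {
    w / v - XtVi %*% (XtViXinv %*% crossprod(XtVi, w))
  }
  Py <- Pfun(ystar)
  ## tr(P M) for M = diag(md) in the rotated basis
  trP <- function(md) {
    sum(md / v) - sum(diag(XtViXinv %*% crossprod(Xstar, Xstar * (md / v^2))))
  }
  list(v = v, Py = Py, Pfun = Pfun, trP = trP)
}

#' Univariate GREML variance components
#'
#' Fits y = Xb + g + e with var(y) = A*VG + I*VE by restricted maximum
#' likelihood: one EM-REML step from VG = VE = Vp/2, then average-information
#' updates to a relative log-likelihood tolerance of 1e-8 (at most `maxIter`
#' iterations). Standard errors come from the inverse AI matrix, with the
#' delta method for VG/Vp. In constrained mode components are truncated at
#' 1e-6 * Vp, mirroring standard GREML tooling.
#'
#' Missing phenotypes are dropped (with the matching GRM rows/columns).
#' Non-convergence flags the result rather than raising; a singular AI
#' matrix triggers a fallback EM step.
#'
#' @param y numeric phenotype vector.
#' @param X covariate matrix including the intercept, or `NULL` for an
#'   intercept only.
#' @param grm a \linkS4class{GRM}.
#' @param constrain keep components non-negative (default `TRUE`).
#' @param maxIter,tol iteration cap and relative logL tolerance.
#' @return A \linkS4class{VarianceComponents}.
#' @export
remlUnivariate <- function(y, X = NULL, grm, constrain = TRUE,
                           maxIter = 100L, tol = 1e-8) {
  a <- grmValues(grm)
  n0 <- length(y)
  if (nrow(a) != n0) stop("phenotype and GRM dimensions differ")
  if (is.null(X)) X <- matrix(1, n0, 1)
  X <- as.matrix(X)
  if (nrow(X) != n0) stop("covariate and phenotype dimensions differ")
  ok <- !is.na(y) & !rowSums(is.na(X))
  y <- y[ok]; X <- X[ok, , drop = FALSE]; a <- a[ok, ok, drop = FALSE]
  n <- length(y); p <- qr(X)$rank
  if (p < ncol(X)) stop("covariate matrix is rank deficient")

  ed <- eigen(a, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  ystar <- drop(crossprod(ed$vectors, y))
  Xstar <- crossprod(ed$vectors, X)

  vp <- var(y)
  floorV <- 1e-6 * vp
  theta <- c(vg = vp / 2, ve = vp / 2)

  clamp <- function(th) {
    if (constrain) pmax(th, floorV) else th
  }

  logL <- .remlLogLik(ystar, Xstar, d, theta[1], theta[2])
  converged <- FALSE
  constrainedFlag <- FALSE
  iter <- 0L

  for (it in seq_len(maxIter)) {
    iter <- it
    parts <- .remlParts(ystar, Xstar, d, theta[1], theta[2])
    Py <- parts$Py
    yPAPy <- sum(d * Py^2)
    yPPy <- sum(Py^2)
    score <- 0.5 * c(yPAPy - parts$trP(d), yPPy - parts$trP(rep(1, n)))

    if (it == 1L) {
      ## EM warm-up step
      newTheta <- clamp(c(
        theta[1] + theta[1]^2 / n * (yPAPy - parts$trP(d)),
        theta[2] + theta[2]^2 / n * (yPPy - parts$trP(rep(1, n)))))
    } else {
      APy <- d * Py
      PAPy <- parts$Pfun(APy)
      PPy <- parts$Pfun(Py)
      AI <- 0.5 * matrix(c(sum(APy * PAPy), sum(APy * PPy),
                           sum(APy * PPy), sum(Py * PPy)), 2, 2)
      delta <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (is.null(delta)) {
        ## singular AI: fall back to an EM step
        delta <- c(theta[1]^2 / n * (yPAPy - parts$trP(d)),
                   theta[2]^2 / n * (yPPy - parts$trP(rep(1, n))))
      }
      newTheta <- clamp(theta + delta)
      if (constrain && !is.null(delta)) {
        ## active set: with one component pinned at its floor, re-solve the
        ## AI step for the free component so the boundary does not stall it
        pinned <- (theta + delta) < floorV
        if (xor(pinned[1], pinned[2])) {
          i <- which(!pinned); j <- which(pinned)
          dj <- floorV - theta[j]
          di <- (score[i] - AI[i, j] * dj) / AI[i, i]
          if (is.finite(di)) {
            newTheta <- theta
            newTheta[j] <- floorV
            newTheta[i] <- max(theta[i] + di, floorV)
          }
        }
      }
    }
    ## monotone ascent: halve the move until the likelihood does not drop
    newLogL <- .remlLogLik(ystar, Xstar, d, newTheta[1], newTheta[2])
    half <- 0L
    while ((!is.finite(newLogL) || newLogL < logL - 1e-10) && half < 30L) {
      newTheta <- clamp((theta + newTheta) / 2)
      newLogL <- .remlLogLik(ystar, Xstar, d, newTheta[1], newTheta[2])
      half <- half + 1L
    }
    if (!is.finite(newLogL)) break
    theta <- newTheta
    if (constrain && any(theta <= floorV * (1 + 1e-9)))
      constrainedFlag <- TRUE
    if (it > 1L && abs(newLogL - logL) < tol * (abs(logL) + 1)) {
      logL <- newLogL
      converged <- TRUE
      break
    }
    logL <- newLogL
  }

  ## SEs from the AI matrix at the optimum
  parts <- .remlParts(ystar, Xstar, d, theta[1], theta[2])
  Py <- parts$Py
  APy <- d * Py
  PAPy <- parts$Pfun(APy)
  PPy <- parts$Pfun(Py)
  AI <- 0.5 * matrix(c(sum(APy * PAPy), sum(APy * PPy),
                       sum(APy * PPy), sum(Py * PPy)), 2, 2)
  AIinv <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, 2, 2))
  vg <- theta[1]; ve <- theta[2]; vpHat <- vg + ve
  grad <- c(ve, -vg) / vpHat^2
  seRatio <- sqrt(max(0, drop(grad %*% AIinv %*% grad)))

  new("VarianceComponents",
      VG = unname(vg), VE = unname(ve), Vp = unname(vpHat),
      ratio = unname(min(1, max(0, vg / vpHat))),
      seRatio = unname(seRatio),
      seVG = sqrt(max(0, AIinv[1, 1])), seVE = sqrt(max(0, AIinv[2, 2])),
      logL = logL, nIter = iter,
      converged = converged, constrained = constrainedFlag)
}

#' Restricted log-likelihood of the no-genetics null model
#'
#' REML fit of y = Xb + e (VG omitted). The residual variance has the closed
#' form RSS / (n - p); the log-likelihood is evaluated with the same constant
#' convention as [remlUnivariate()], so the two are directly comparable in a
#' likelihood-ratio test.
#'
#' @inheritParams remlUnivariate
#' @return list with `logL` and `sigma2`.
#' @export
remlNull <- function(y, X = NULL) {
  n0 <- length(y)
  if (is.null(X)) X <- matrix(1, n0, 1)
  X <- as.matrix(X)
  ok <- !is.na(y) & !rowSums(is.na(X))
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  s2 <- rss / (n - p)
  XtX <- crossprod(X)
  logL <- -0.5 * ((n - p) * log(s2) + determinant(XtX)$modulus[1] +
                    (n - p)) - 0.5 * (n - p) * log(2 * pi)
  list(logL = unname(logL), sigma2 = s2)
}

#' Likelihood-ratio test for VG under the boundary mixture null
#'
#' Because VG is constrained to be non-negative, the null distribution of
#' 2*(logL_full - logL_null) is the 50:50 mixture of a point mass at zero and
#' chi-square(1): p = 0.5 * P(chi2_1 >= stat) for stat > 0 and p = 1 at
#' stat = 0. The alpha = 0.05 critical value of this mixture is the 0.90
#' quantile of chi-square(1), 2.7055.
#'
#' @param full a \linkS4class{VarianceComponents} from [remlUnivariate()].
#' @param nullLogL restricted log-likelihood of the matching null model
#'   (same fixed effects, VG omitted), e.g. from [remlNull()].
#' @param tolerance slack allowed before a lower full-model likelihood is
#'   treated as an optimizer fault (a constrained fit sits a hair below the
#'   null when VG is pinned at its positive floor).
#' @return An \linkS4class{LrtResult}.
#' @export
lrtVg <- function(full, nullLogL, tolerance = 1e-3) {
  stat <- 2 * (full@logL - nullLogL)
  if (stat < -tolerance)
    stop(sprintf(
      "full-model logL (%.6f) is below the null (%.6f): optimizer fault",
      full@logL, nullLogL))
  stat <- max(0, stat)
  p <- if (stat == 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  new("LrtResult", statistic = stat, df = 1, pValue = p)
}

#' Critical value of the boundary mixture null
#'
#' Solves 0.5 * P(chi2_1 >= c) = alpha; at alpha = 0.05 this is 2.7055.
#'
#' @param alpha significance level.
#' @return the critical value.
#' @export
mixtureCriticalValue <- function(alpha = 0.05) {
  qchisq(1 - 2 * alpha, df = 1)
}
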