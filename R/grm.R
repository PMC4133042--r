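## Genomic relationship matrix in GCTA conventions, relatedness pruning,
## principal components, and the GCTA-style text exchange format.

#' Compute the genomic relationship matrix
#'
#' GCTA-style GRM on standardized dosages: for individuals j, k
#' \deqn{A_{jk} = \frac{1}{N_{jk}} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
#' {2 p_i (1 - p_i)}}
#' with allele frequencies estimated from the sample. Missing dosages are
#' imputed at the SNP mean 2p (contributing zero to the numerator) and
#' excluded from the per-pair SNP count \eqn{N_{jk}}.
#'
#' @param g a \linkS4class{GenotypeData}; MAF filtering must already have
#'   removed monomorphic SNPs.
#' @return A \linkS4class{GRM}.
#' @export
computeGRM <- function(g) {
  d <- dosages(g)
  p <- rowMeans(d, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP reached computeGRM: apply the MAF filter first")
  w <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  obs <- !is.na(w)
  w[!obs] <- 0
  a <- crossprod(w)
  npair <- crossprod(obs * 1)
  if (any(npair == 0)) stop("a sample pair shares no non-missing SNPs")
  a <- a / npair
  a <- (a + t(a)) / 2
  new("GRM", values = unname(a), nsnp = matrix(as.integer(npair), nrow(a)),
      sampleIds = sampleIds(g))
}

#' Prune related individuals
#'
#' Greedy removal until no retained pair has relatedness above `cutoff`:
#' repeatedly drop the individual participating in the most over-cutoff
#' pairs, ties broken by the lower sample index. Deterministic.
#'
#' @param grm a \linkS4class{GRM}.
#' @param cutoff maximum tolerated off-diagonal relatedness (default 0.05).
#' @return list with `keep` (logical vector), `sampleIds` (retained ids) and
#'   `removed` (indices dropped, in removal order).
#' @export
pruneRelated <- function(grm, cutoff = 0.05) {
  a <- grmValues(grm)
  n <- nrow(a)
  over <- a > cutoff
  diag(over) <- FALSE
  keep <- rep(TRUE, n)
  removed <- integer(0)
  repeat {
    deg <- rowSums(over[, keep, drop = FALSE]) * keep
    if (!any(deg > 0)) break
    drop <- which.max(deg)          # which.max takes the lowest index on ties
    keep[drop] <- FALSE
    removed <- c(removed, drop)
  }
  list(keep = keep,
       sampleIds = sampleIds(grm)[keep, , drop = FALSE],
       removed = removed)
}

#' Principal components of the relatedness matrix
#'
#' Top-k eigenvectors of the double-centered GRM, ordered by descending
#' eigenvalue. Sign convention: the largest-magnitude loading of each
#' component is positive. With a degenerate (equal-eigenvalue) spectrum the
#' eigen decomposition's ordering is kept; the vectors are still orthonormal.
#'
#' @param grm a \linkS4class{GRM}.
#' @param k number of components (default 10, must be < n).
#' @return n x k matrix of orthonormal component scores, with the
#'   eigenvalues in `attr(, "values")`.
#' @export
grmPCA <- function(grm, k = 10) {
  a <- grmValues(grm)
  n <- nrow(a)
  if (k >= n) stop("invalid config: k must be smaller than the sample size")
  h <- diag(n) - matrix(1 / n, n, n)
  ev <- eigen(h %*% a %*% h, symmetric = TRUE)
  vec <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  colnames(vec) <- sprintf("PC%d", seq_len(k))
  rownames(vec) <- sampleIds(grm)$IID
  attr(vec, "values") <- ev$values[seq_len(k)]
  vec
}

#' Write / read a GRM in GCTA text format
#'
#' `<prefix>.grm.txt` holds tab-separated rows `(index1, index2, nsnp,
#' value)` for the lower triangle including the diagonal, 1-based, and
#' `<prefix>.grm.id` holds `(FID, IID)` per sample. Round-trips are lossless
#' to the printed precision (1e-6 or better).
#'
#' @param grm a \linkS4class{GRM}.
#' @param prefix file path prefix.
#' @return `writeGRM` returns the prefix invisibly; `readGRM` a
#'   \linkS4class{GRM}.
#' @export
writeGRM <- function(grm, prefix) {
  a <- grmValues(grm)
  ns <- grmNsnp(grm)
  n <- nrow(a)
  idx <- which(lower.tri(a, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  rows <- data.frame(i = idx[, 1], j = idx[, 2],
                     nsnp = ns[idx], value = sprintf("%.8g", a[idx]))
  write.table(rows, paste0(prefix, ".grm.txt"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sampleIds(grm), paste0(prefix, ".grm.id"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname writeGRM
#' @export
readGRM <- function(prefix) {
  tri <- read.table(paste0(prefix, ".grm.txt"), header = FALSE,
                    col.names = c("i", "j", "nsnp", "value"))
  ids <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                    col.names = c("FID", "IID"),
                    colClasses = "character")
  n <- max(tri$i)
  if (nrow(ids) != n)
    stop(sprintf("GRM id file has %d rows but the matrix has %d samples",
                 nrow(ids), n))
  a <- matrix(0, n, n)
  ns <- matrix(0L, n, n)
  a[cbind(tri$i, tri$j)] <- tri$value
  ns[cbind(tri$i, tri$j)] <- tri$nsnp
  a[upper.tri(a)] <- t(a)[upper.tri(a)]
  ns[upper.tri(ns)] <- t(ns)[upper.tri(ns)]
  new("GRM", values = a, nsnp = ns, sampleIds = ids)
}
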