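## PLINK text PED/MAP reader and writer.
## Dialect: whitespace-delimited; PED has 6 leading columns
## (FID IID PAT MAT SEX PHENO) then two allele columns per SNP, missing
## genotype coded "0 0"; MAP has chrom, id, cM, bp.

.VALID_ALLELES <- c("A", "C", "G", "T", "0")

#' Read genotypes from PLINK text PED/MAP files
#'
#' Alleles are recoded to minor-allele dosage: for each SNP the less frequent
#' observed allele is counted (ties broken alphabetically), so a monomorphic
#' SNP gets frequency 0 and dosage 0 everywhere. `0 0` becomes missing.
#'
#' @param pedPath,mapPath paths to the PED and MAP files.
#' @return A \linkS4class{GenotypeData}.
#' @export
readPlink <- function(pedPath, mapPath) {
  if (!file.exists(pedPath)) stop("PED file not found: ", pedPath)
  if (!file.exists(mapPath)) stop("MAP file not found: ", mapPath)
  map <- read.table(mapPath, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cM", "pos"))
  m <- nrow(map)
  lines <- readLines(pedPath)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (!n) stop("PED file is empty")
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  dosage <- matrix(NA_integer_, m, n)
  fid <- iid <- character(n)
  alleleMat1 <- matrix(NA_character_, m, n)
  alleleMat2 <- matrix(NA_character_, m, n)
  for (j in seq_len(n)) {
    f <- fields[[j]]
    if (length(f) != want)
      stop(sprintf("PED line %d has %d fields, expected %d (ragged row)",
                   j, length(f), want))
    fid[j] <- f[1]; iid[j] <- f[2]
    al <- f[-(1:6)]
    bad <- which(!(al %in% .VALID_ALLELES))
    if (length(bad))
      stop(sprintf("PED line %d: invalid allele code '%s' (allowed: A,C,G,T,0)",
                   j, al[bad[1]]))
    alleleMat1[, j] <- al[c(TRUE, FALSE)]
    alleleMat2[, j] <- al[c(FALSE, TRUE)]
  }
  halfMissing <- (alleleMat1 == "0") != (alleleMat2 == "0")
  if (any(halfMissing))
    stop(sprintf("PED line %d: half-missing genotype",
                 which(colSums(halfMissing) > 0)[1]))
  a1 <- character(m); a2 <- character(m)
  for (i in seq_len(m)) {
    al <- c(alleleMat1[i, ], alleleMat2[i, ])
    al <- al[al != "0"]
    tab <- sort(table(al))
    obs <- names(tab)
    if (length(obs) > 2)
      stop(sprintf("SNP %s: more than two alleles observed", map$id[i]))
    if (length(obs) == 0) { minor <- "0"; major <- "0" }
    else if (length(obs) == 1) { minor <- "0"; major <- obs }
    else if (tab[[1]] == tab[[2]]) {
      minor <- sort(obs)[1]; major <- sort(obs)[2]
    } else { minor <- obs[1]; major <- obs[2] }
    a1[i] <- minor; a2[i] <- major
    cnt <- (alleleMat1[i, ] == minor) + (alleleMat2[i, ] == minor)
    cnt[alleleMat1[i, ] == "0"] <- NA_integer_
    dosage[i, ] <- cnt
  }
  meta <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                     a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  GenotypeData(dosage, meta, data.frame(FID = fid, IID = iid,
                                        stringsAsFactors = FALSE))
}

#' Write genotypes as PLINK text PED/MAP files
#'
#' The counted (minor) allele `a1` is written `dosage` times, the other
#' allele fills the remainder; missing dosage becomes `0 0`.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return the prefix, invisibly.
#' @export
writePlink <- function(g, prefix) {
  d <- dosages(g)
  meta <- snpMeta(g)
  ids <- sampleIds(g)
  m <- nrow(d); n <- ncol(d)
  map <- data.frame(meta$chrom, meta$id, 0, meta$pos)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  geno <- matrix("0", 2L * m, n)
  odd <- seq(1L, 2L * m, by = 2L)
  for (i in seq_len(m)) {
    di <- d[i, ]
    g1 <- ifelse(is.na(di), "0", ifelse(di >= 1, meta$a1[i], meta$a2[i]))
    g2 <- ifelse(is.na(di), "0", ifelse(di == 2, meta$a1[i], meta$a2[i]))
    geno[odd[i], ] <- g1
    geno[odd[i] + 1L, ] <- g2
  }
  ped <- cbind(ids$FID, ids$IID, "0", "0", "0", "-9", t(geno))
  write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
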