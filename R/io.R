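#' Read PLINK text PED/MAP files
#'
#' PED columns: FID IID PAT MAT SEX PHENO followed by two allele columns
#' per SNP ("0" = missing allele). MAP columns: chromosome, SNP id, cM,
#' bp (1-based). The coded allele of each SNP is the first allele observed
#' in file order (scanning samples top to bottom, first then second allele
#' column); this is deterministic and documented because the minor-allele
#' convention depends on frequencies that change under filtering, and all
#' kinship quantities are invariant to the choice. Heterozygotes code 1/2
#' regardless of allele order; "0 0" codes missing. The FID column is kept
#' as the sample's line label.
#'
#' @param pedPath,mapPath file paths.
#' @return a \linkS4class{GenotypeData}, SNPs sorted by chromosome and
#'   position.
#' @export
readPedMap <- function(pedPath, mapPath) {
  map <- data.table::fread(mapPath, header = FALSE, data.table = FALSE,
                           col.names = c("chromosome", "snp", "cM", "bp"))
  nf <- count.fields(pedPath)
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged PED file: line %d has %d fields, expected %d",
                 bad, nf[bad], nf[1]))
  }
  if (nf[1] != 6 + 2 * nrow(map))
    stop(sprintf("PED has %d genotype columns but MAP lists %d SNPs",
                 nf[1] - 6, nrow(map)))
  ped <- data.table::fread(pedPath, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  n <- nrow(ped); m <- nrow(map)
  codes <- matrix(NA_real_, n, m)
  codedAllele <- character(m); otherAllele <- rep(NA_character_, m)
  for (k in seq_len(m)) {
    a1 <- ped[[5 + 2 * k]]
    a2 <- ped[[6 + 2 * k]]
    seen <- as.vector(rbind(a1, a2))          # file order: a1[1], a2[1], a1[2], ...
    seen <- seen[seen != "0"]
    if (length(seen)) {
      codedAllele[k] <- seen[1]
      rest <- seen[seen != seen[1]]
      if (length(rest)) otherAllele[k] <- rest[1]
      miss <- a1 == "0" | a2 == "0"
      codes[, k] <- ((a1 == codedAllele[k]) + (a2 == codedAllele[k])) / 2
      codes[miss, k] <- NA_real_
    } else {
      codedAllele[k] <- "A"                   # SNP entirely missing
    }
  }
  rownames(codes) <- ped[[2]]
  colnames(codes) <- map$snp
  o <- order(map$chromosome, map$bp)
  new("GenotypeData",
      codes = codes[, o, drop = FALSE],
      line = ped[[1]],
      chromosome = as.integer(map$chromosome[o]),
      positionBp = as.integer(map$bp[o]),
      positionCM = as.numeric(map$cM[o]),
      codedAllele = codedAllele[o],
      otherAllele = otherAllele[o])
}

#' Write PLINK text PED/MAP files
#'
#' Inverse of \code{\link{readPedMap}}: code 1 writes two coded alleles,
#' 1/2 one of each (coded first), 0 two other alleles, NA writes "0 0".
#' Parent and sex columns are filled from \code{pedigree} when given,
#' otherwise zeroed; phenotype is -9. A SNP whose other allele was never
#' observed falls back to "B".
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param pedPath,mapPath output paths.
#' @param pedigree optional \linkS4class{Pedigree} supplying PAT/MAT/SEX.
#' @export
writePedMap <- function(genotypes, pedPath, mapPath, pedigree = NULL) {
  codes <- genotypeCodes(genotypes)
  n <- nrow(codes); m <- ncol(codes)
  coded <- genotypes@codedAllele
  other <- genotypes@otherAllele
  other[is.na(other)] <- "B"
  a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
  for (k in seq_len(m)) {
    x <- codes[, k]
    a1[, k] <- ifelse(is.na(x), "0", ifelse(x >= 0.5, coded[k], other[k]))
    a2[, k] <- ifelse(is.na(x), "0", ifelse(x == 1, coded[k], other[k]))
  }
  ids <- rownames(codes)
  pat <- mat <- rep("0", n); sex <- rep("0", n)
  if (!is.null(pedigree)) {
    at <- match(ids, pedigree@id)
    pat <- ifelse(is.na(pedigree@sire[at]), "0", pedigree@sire[at])
    mat <- ifelse(is.na(pedigree@dam[at]), "0", pedigree@dam[at])
    sex <- c(M = "1", F = "2")[pedigree@sex[at]]
    sex[is.na(sex)] <- "0"
  }
  geno <- matrix("", n, 2 * m)
  geno[, seq(1, 2 * m, by = 2)] <- a1
  geno[, seq(2, 2 * m, by = 2)] <- a2
  out <- cbind(genotypes@line, ids, pat, mat, sex, "-9", geno)
  data.table::fwrite(as.data.frame(out), pedPath, sep = " ",
                     col.names = FALSE, quote = FALSE)
  mapOut <- data.frame(genotypes@chromosome, colnames(codes),
                       genotypes@positionCM, genotypes@positionBp)
  data.table::fwrite(mapOut, mapPath, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(pedPath)
}
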