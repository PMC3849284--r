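#' Per-SNP Mendelian (opposing-homozygote) error counts
#'
#' For every recorded parent-offspring duo with both members genotyped,
#' a SNP where the two are homozygous for different alleles (codes 0
#' against 1) is a Mendelian impossibility and counts one error. Duos with
#' a missing genotype at a SNP are skipped at that SNP. SNPs accumulating
#' many such errors indicate bad assays or recorded-pedigree mistakes.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param pedigree a \linkS4class{Pedigree}; both sire-offspring and
#'   dam-offspring duos are used when genotyped.
#' @return integer vector of error counts per SNP, with the number of
#'   genotyped duos as attribute \code{nDuos}.
#' @export
mendelianErrorCounts <- function(genotypes, pedigree) {
  codes <- genotypeCodes(genotypes)
  ids <- rownames(codes)
  duos <- rbind(
    cbind(pedigree@sire, pedigree@id),
    cbind(pedigree@dam, pedigree@id))
  duos <- duos[!is.na(duos[, 1]) & duos[, 1] %in% ids & duos[, 2] %in% ids, ,
               drop = FALSE]
  counts <- integer(ncol(codes))
  if (nrow(duos) == 0) {
    warning("no genotyped parent-offspring duo; all Mendelian counts are 0")
  } else {
    for (r in seq_len(nrow(duos))) {
      xp <- codes[duos[r, 1], ]
      xo <- codes[duos[r, 2], ]
      opp <- (xp == 0 & xo == 1) | (xp == 1 & xo == 0)
      opp[is.na(opp)] <- FALSE    # duo skipped at SNPs with a missing genotype
      counts <- counts + opp
    }
  }
  structure(as.integer(counts), names = colnames(codes), nDuos = nrow(duos))
}

#' Apply the marker and individual quality-control filters
#'
#' Filters run in sequence, each SNP attributed to the first filter that
#' removes it: (1) SNPs with \code{mendelMax + 1} or more opposing-homozygote
#' errors across parent-offspring duos; (2) SNPs with MAF strictly below
#' \code{mafMin} in at least one line (alleles counted among non-missing
#' genotypes within line); (3) SNPs with call rate strictly below
#' \code{callrateMin}; (4) SNPs on non-autosomal chromosomes; then (5)
#' individuals whose missing-genotype fraction (over surviving SNPs) is
#' strictly above \code{indivMissingMax}. Boundary cases follow the
#' strict inequalities: a SNP with MAF exactly \code{mafMin} is retained.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param pedigree a \linkS4class{Pedigree} for the Mendelian filter; NULL
#'   skips that filter.
#' @param mendelMax largest tolerated Mendelian error count (default 29,
#'   i.e. SNPs with 30 or more errors are removed).
#' @param mafMin minor-allele-frequency threshold (default 0.05).
#' @param callrateMin SNP call-rate threshold (default 0.95).
#' @param indivMissingMax individual missingness threshold (default 0.05).
#' @param autosomes integer chromosome codes considered autosomal
#'   (default 1:18); SNPs elsewhere are removed as sex-chromosome markers.
#' @return list with \code{genotypes} (filtered) and \code{report}
#'   (a \linkS4class{QCReport}).
#' @export
applyQC <- function(genotypes, pedigree = NULL, mendelMax = 29,
                    mafMin = 0.05, callrateMin = 0.95,
                    indivMissingMax = 0.05, autosomes = 1:18) {
  stopifnot(mendelMax >= 0, mafMin >= 0, mafMin < 1,
            callrateMin > 0, callrateMin <= 1,
            indivMissingMax >= 0, indivMissingMax <= 1)
  codes <- genotypeCodes(genotypes)
  snps <- colnames(codes)
  alive <- rep(TRUE, length(snps))

  removedMendel <- character(0)
  if (!is.null(pedigree)) {
    mc <- mendelianErrorCounts(genotypes, pedigree)
    hit <- alive & mc > mendelMax
    removedMendel <- snps[hit]
    alive[hit] <- FALSE
  }

  # MAF within each line, allele counting among non-missing genotypes
  mafHit <- rep(FALSE, length(snps))
  for (i in split(seq_len(nrow(codes)), genotypes@line)) {
    p <- colMeans(codes[i, , drop = FALSE], na.rm = TRUE)
    maf <- pmin(p, 1 - p)
    mafHit <- mafHit | is.na(maf) | maf < mafMin
  }
  hit <- alive & mafHit
  removedMaf <- snps[hit]
  alive[hit] <- FALSE

  callrate <- colMeans(!is.na(codes))
  hit <- alive & callrate < callrateMin
  removedCallrate <- snps[hit]
  alive[hit] <- FALSE

  hit <- alive & !(genotypes@chromosome %in% autosomes)
  removedSexchrom <- snps[hit]
  alive[hit] <- FALSE

  if (!any(alive)) stop("no SNP survives quality control")
  kept <- genotypes[, which(alive)]

  indivMiss <- rowMeans(is.na(genotypeCodes(kept)))
  badIndiv <- indivMiss > indivMissingMax
  removedIndividuals <- rownames(codes)[badIndiv]
  if (all(badIndiv)) stop("no individual survives quality control")
  kept <- kept[which(!badIndiv), ]

  report <- new("QCReport",
                removedMendel = removedMendel,
                removedMaf = removedMaf,
                removedCallrate = removedCallrate,
                removedSexchrom = removedSexchrom,
                removedIndividuals = removedIndividuals,
                survivingSnps = ncol(kept),
                survivingSamples = nrow(kept),
                thresholds = c(mendelMax = mendelMax, mafMin = mafMin,
                               callrateMin = callrateMin,
                               indivMissingMax = indivMissingMax))
  list(genotypes = kept, report = report)
}
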