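#' Verify recorded sire-offspring pairs by opposing homozygotes
#'
#' A true parent and offspring can never be homozygous for different
#' alleles at the same SNP (absent genotyping error), while an unrelated
#' male shows opposing homozygotes at a rate of 2 p^2 (1-p)^2 per SNP
#' (about 12.5\% at p = 0.5). A pair is confirmed when its mismatch rate
#' over jointly non-missing SNPs is strictly below the threshold; pairs
#' with fewer than \code{minSnps} comparable SNPs get verdict "withheld".
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param pairs two-column matrix or data.frame (sire id, offspring id);
#'   defaults to every recorded sire-offspring pair of \code{pedigree}
#'   with both members genotyped.
#' @param pedigree optional \linkS4class{Pedigree} used to build
#'   \code{pairs} when not supplied.
#' @param mismatchThreshold confirm when mismatch rate < this (default
#'   0.01, tolerant of genotyping error yet far below the unrelated-male
#'   rate).
#' @param minSnps minimum jointly non-missing SNPs for a verdict
#'   (default 100).
#' @return data.frame: sire, offspring, nSnpsCompared,
#'   nOpposingHomozygotes, mismatchRate, verdict (confirmed / rejected /
#'   withheld).
#' @export
checkPaternity <- function(genotypes, pairs = NULL, pedigree = NULL,
                           mismatchThreshold = 0.01, minSnps = 100) {
  codes <- genotypeCodes(genotypes)
  ids <- rownames(codes)
  if (is.null(pairs)) {
    if (is.null(pedigree)) stop("supply either pairs or a pedigree")
    ok <- !is.na(pedigree@sire) & pedigree@sire %in% ids & pedigree@id %in% ids
    pairs <- cbind(pedigree@sire[ok], pedigree@id[ok])
  }
  pairs <- as.matrix(pairs)
  out <- data.frame(sire = pairs[, 1], offspring = pairs[, 2],
                    nSnpsCompared = 0L, nOpposingHomozygotes = 0L,
                    mismatchRate = NA_real_, verdict = "withheld",
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pairs))) {
    xs <- codes[pairs[r, 1], ]
    xo <- codes[pairs[r, 2], ]
    ok <- !is.na(xs) & !is.na(xo)
    nC <- sum(ok)
    nO <- sum((xs == 0 & xo == 1) | (xs == 1 & xo == 0), na.rm = TRUE)
    out$nSnpsCompared[r] <- nC
    out$nOpposingHomozygotes[r] <- nO
    if (nC >= minSnps) {
      out$mismatchRate[r] <- nO / nC
      out$verdict[r] <- if (nO / nC < mismatchThreshold) "confirmed" else "rejected"
    }
  }
  out
}
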