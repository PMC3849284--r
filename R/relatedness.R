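#' Coded-allele frequencies by allele counting
#'
#' The frequency of the coded allele equals the mean genotype code over
#' non-missing samples (codes 0, 1/2, 1 are half the allele dose). The
#' population whose alleles are counted defines the base population of all
#' downstream inbreeding and kinship estimates; here that is the current
#' genotyped sample, optionally within line.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param perLine if TRUE, return a list of frequency vectors, one per line.
#' @return named numeric vector of frequencies (or list of them), with an
#'   \code{nObs} attribute giving non-missing counts.
#' @export
alleleFrequencies <- function(genotypes, perLine = FALSE) {
  codes <- genotypeCodes(genotypes)
  one <- function(x) {
    nObs <- colSums(!is.na(x))
    if (any(nObs == 0))
      stop(sprintf("SNP(s) with all genotypes missing: %s",
                   paste(head(colnames(x)[nObs == 0], 5), collapse = ", ")))
    p <- colMeans(x, na.rm = TRUE)
    attr(p, "nObs") <- nObs
    p
  }
  if (!perLine) return(one(codes))
  lapply(split(seq_len(nrow(codes)), genotypes@line),
         function(i) one(codes[i, , drop = FALSE]))
}

#' Genomic kinship matrix (allele-frequency-weighted IBS)
#'
#' For individuals i and j, g_ij is the average over SNPs non-missing in
#' both of (x_i - p)(x_j - p) / (p (1 - p)), with x the 0/1/2-halved
#' genotype code and p the coded-allele frequency. Expectations under this
#' weighting: (1 + F)/2 on the diagonal, 0.25 for parent-offspring and
#' full sibs, 0.125 for half sibs, 0 for unrelated pairs (frequencies from
#' the base population). The value is invariant to swapping which allele is
#' coded at any SNP.
#'
#' @param genotypes a \linkS4class{GenotypeData}; every SNP must have
#'   0 < p < 1 (guaranteed downstream of the MAF filter).
#' @param freq coded-allele frequencies; defaults to sample frequencies
#'   from \code{\link{alleleFrequencies}}. Supply true founder frequencies
#'   for simulator calibration checks, or line-specific frequencies for
#'   within-line analyses.
#' @param snps optional SNP ids (or index) restricting the computation,
#'   e.g. a pruned linkage-equilibrium set.
#' @param weights optional non-negative per-SNP multiplicities (after any
#'   \code{snps} subsetting); bootstrap-duplicated SNPs enter the average
#'   with their multiplicity.
#' @return a \linkS4class{KinshipMatrix}.
#' @export
genomicKinship <- function(genotypes, freq = NULL, snps = NULL, weights = NULL) {
  if (!is.null(snps)) genotypes <- genotypes[, snps]
  codes <- genotypeCodes(genotypes)
  if (is.null(freq)) freq <- alleleFrequencies(genotypes)
  p <- .matchFreq(freq, colnames(codes))
  if (any(p <= 0 | p >= 1))
    stop("kinship requires 0 < p < 1 at every SNP; filter monomorphic SNPs first")
  if (is.null(weights)) weights <- rep(1, ncol(codes))
  stopifnot(length(weights) == ncol(codes), all(weights >= 0))
  W <- sweep(codes, 2, p) / rep(sqrt(p * (1 - p)), each = nrow(codes))
  obs <- !is.na(W)
  W[!obs] <- 0
  num <- tcrossprod(sweep(W, 2, weights, "*"), W)
  den <- tcrossprod(sweep(obs + 0, 2, weights, "*"), obs + 0)
  if (any(den == 0))
    stop("pair(s) with no jointly non-missing SNP; kinship undefined")
  new("KinshipMatrix", values = num / den, nSnps = den)
}

.matchFreq <- function(freq, snpNames) {
  if (!is.null(names(freq))) {
    miss <- setdiff(snpNames, names(freq))
    if (length(miss)) stop("frequencies missing for some SNPs")
    return(unname(freq[snpNames]))
  }
  if (length(freq) != length(snpNames))
    stop("unnamed frequency vector must match SNP count")
  as.numeric(freq)
}

#' Genomic inbreeding from the kinship diagonal
#'
#' F_i = 2 g_ii - 1, since E[g_ii] = (1 + F)/2 under the 0/1/2-halved
#' coding. Individuals more heterozygous than expected under
#' Hardy-Weinberg equilibrium in the base population get negative values.
#'
#' @param kinship a \linkS4class{KinshipMatrix}, or a
#'   \linkS4class{GenotypeData} (computed per individual without forming
#'   the full matrix, which is cheaper when only inbreeding is needed).
#' @param ... passed on to \code{\link{genomicKinship}} machinery when
#'   \code{kinship} is a GenotypeData (\code{freq}, \code{snps},
#'   \code{weights}).
#' @return named numeric vector of inbreeding coefficients.
#' @export
genomicInbreeding <- function(kinship, ...) {
  if (is(kinship, "KinshipMatrix")) {
    v <- diag(kinship@values)
    return(2 * v - 1)
  }
  .genomicInbreedingDirect(kinship, ...)
}

# diagonal-only path: per-individual weighted mean of (x - p)^2 / (p q)
.genomicInbreedingDirect <- function(genotypes, freq = NULL, snps = NULL,
                                     weights = NULL) {
  if (!is.null(snps)) genotypes <- genotypes[, snps]
  codes <- genotypeCodes(genotypes)
  if (is.null(freq)) freq <- alleleFrequencies(genotypes)
  p <- .matchFreq(freq, colnames(codes))
  if (is.null(weights)) weights <- rep(1, ncol(codes))
  W2 <- (sweep(codes, 2, p) / rep(sqrt(p * (1 - p)), each = nrow(codes)))^2
  obs <- !is.na(W2)
  W2[!obs] <- 0
  g <- as.vector(W2 %*% weights) / as.vector((obs + 0) %*% weights)
  setNames(2 * g - 1, rownames(codes))
}

#' Pairwise kinship values for a list of pairs
#'
#' Convenience extractor from a \linkS4class{KinshipMatrix}.
#'
#' @param kinship a \linkS4class{KinshipMatrix}.
#' @param pairs two-column matrix or data.frame of sample ids.
#' @return numeric vector of g values per pair.
#' @export
pairKinship <- function(kinship, pairs) {
  pairs <- as.matrix(pairs)
  ids <- rownames(kinship@values)
  i <- match(pairs[, 1], ids); j <- match(pairs[, 2], ids)
  if (anyNA(i) || anyNA(j)) stop("pair ids not found in kinship matrix")
  kinship@values[cbind(i, j)]
}
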