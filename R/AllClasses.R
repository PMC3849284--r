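#' @import methods
#' @importFrom stats cor rbinom rpois runif sd quantile median setNames
#' @importFrom utils head count.fields
NULL

#' GenotypeData: SNP genotypes with marker map and sample metadata
#'
#' Container for biallelic SNP genotypes of a set of individuals. Genotypes
#' are stored as numeric codes 0, 1/2 and 1: 1 for the homozygote of the
#' coded allele, 1/2 for the heterozygote, 0 for the other homozygote, and
#' \code{NA} for a missing genotype. The coded allele is recorded per SNP so
#' that files can be round-tripped losslessly; all downstream kinship
#' quantities are invariant to which allele is coded (swapping alleles maps
#' code x to 1 - x and frequency p to 1 - p, leaving the weighted products
#' unchanged).
#'
#' @slot codes numeric matrix, samples x SNPs, values in \{0, 0.5, 1, NA\};
#'   rownames are sample ids, colnames SNP ids.
#' @slot line character, breeding line / population label per sample.
#' @slot chromosome integer chromosome code per SNP (autosomes are positive
#'   integers; sex chromosomes may use any code outside the autosome set).
#' @slot positionBp integer 1-based physical position per SNP.
#' @slot positionCM numeric genetic-map coordinate per SNP (centimorgan).
#' @slot codedAllele character, the allele counted by the coding, per SNP.
#' @slot otherAllele character, the second allele, per SNP (may be NA for a
#'   SNP observed monomorphic in a file).
#'
#' @export
setClass("GenotypeData",
  representation(
    codes       = "matrix",
    line        = "character",
    chromosome  = "integer",
    positionBp  = "integer",
    positionCM  = "numeric",
    codedAllele = "character",
    otherAllele = "character"
  )
)

setValidity("GenotypeData", function(object) {
  msg <- character()
  n <- nrow(object@codes); m <- ncol(object@codes)
  if (is.null(rownames(object@codes))) msg <- c(msg, "codes must have sample ids as rownames")
  if (is.null(colnames(object@codes))) msg <- c(msg, "codes must have SNP ids as colnames")
  if (length(object@line) != n) msg <- c(msg, "line labels must match sample count")
  for (sl in c("chromosome", "positionBp", "positionCM", "codedAllele", "otherAllele")) {
    if (length(slot(object, sl)) != m) msg <- c(msg, sprintf("%s must have one entry per SNP", sl))
  }
  bad <- !(object@codes %in% c(0, 0.5, 1) | is.na(object@codes))
  if (any(bad)) msg <- c(msg, "genotype codes must be 0, 0.5, 1 or NA")
  if (anyDuplicated(rownames(object@codes))) msg <- c(msg, "duplicated sample ids")
  if (anyDuplicated(colnames(object@codes))) msg <- c(msg, "duplicated SNP ids")
  # positions must be sorted within chromosome (non-decreasing)
  if (m > 1) {
    o <- order(object@chromosome, object@positionBp)
    if (!identical(o, seq_len(m))) msg <- c(msg, "SNPs must be sorted by chromosome and position")
  }
  if (length(msg)) msg else TRUE
})

#' Pedigree: parent records with sex and line
#'
#' An acyclic pedigree. Unknown parents are \code{NA}. Validity enforces
#' unique ids, acyclicity (every individual must topologically follow its
#' parents) and sex consistency (an id used as a sire must not be recorded
#' female, and vice versa).
#'
#' @slot id character individual ids.
#' @slot sire,dam character parent ids or NA.
#' @slot sex character "M", "F" or NA.
#' @slot line character line label per individual.
#' @export
setClass("Pedigree",
  representation(
    id   = "character",
    sire = "character",
    dam  = "character",
    sex  = "character",
    line = "character"
  )
)

setValidity("Pedigree", function(object) {
  msg <- character()
  n <- length(object@id)
  for (sl in c("sire", "dam", "sex", "line"))
    if (length(slot(object, sl)) != n) msg <- c(msg, sprintf("%s length mismatch", sl))
  if (anyDuplicated(object@id)) msg <- c(msg, sprintf(
    "duplicated id(s): %s", paste(unique(object@id[duplicated(object@id)]), collapse = ", ")))
  miss <- setdiff(c(object@sire, object@dam), c(object@id, NA))
  if (length(miss)) msg <- c(msg, sprintf(
    "parent(s) not defined as individuals: %s", paste(head(miss, 5), collapse = ", ")))
  if (length(msg)) return(msg)
  ord <- try(topoOrder(object), silent = TRUE)
  if (inherits(ord, "try-error")) msg <- c(msg, attr(ord, "condition")$message)
  sireSex <- object@sex[match(object@sire, object@id)]
  damSex  <- object@sex[match(object@dam, object@id)]
  if (any(sireSex %in% "F")) msg <- c(msg, "individual recorded female is used as a sire")
  if (any(damSex %in% "M")) msg <- c(msg, "individual recorded male is used as a dam")
  if (length(msg)) msg else TRUE
})

#' KinshipMatrix: allele-frequency-weighted IBS kinship
#'
#' Symmetric matrix of genomic kinship coefficients g_ij, the average over
#' SNPs (non-missing in both individuals) of
#' (x_i - p)(x_j - p) / (p (1 - p)). The diagonal carries the information
#' needed for genomic inbreeding, F_i = 2 g_ii - 1.
#'
#' @slot values symmetric numeric matrix with sample ids as dimnames.
#' @slot nSnps numeric matrix: per pair, the (weighted) number of SNPs that
#'   entered the average.
#' @export
setClass("KinshipMatrix",
  representation(values = "matrix", nSnps = "matrix")
)

setValidity("KinshipMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  else if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8))) msg <- c(msg, "values must be symmetric")
  if (!identical(dim(object@nSnps), dim(v))) msg <- c(msg, "nSnps dimensions must match values")
  if (any(object@nSnps < 1)) msg <- c(msg, "every pair must share at least one SNP")
  if (length(msg)) msg else TRUE
})

#' QCReport: per-filter removal accounting
#'
#' Records which SNPs and samples each quality-control filter removed.
#' Each SNP is attributed to the first filter that removes it, so counts
#' add up with no double counting.
#'
#' @slot removedMendel,removedMaf,removedCallrate,removedSexchrom character
#'   SNP ids removed by each marker filter, in filter order.
#' @slot removedIndividuals character sample ids removed by the
#'   missingness filter.
#' @slot survivingSnps,survivingSamples integer counts after all filters.
#' @slot thresholds numeric, the thresholds applied.
#' @export
setClass("QCReport",
  representation(
    removedMendel      = "character",
    removedMaf         = "character",
    removedCallrate    = "character",
    removedSexchrom    = "character",
    removedIndividuals = "character",
    survivingSnps      = "integer",
    survivingSamples   = "integer",
    thresholds         = "numeric"
  )
)

#' PanelEvaluation: bootstrap agreement of a reduced panel with the full set
#'
#' Per-replicate Pearson correlations between estimates from a bootstrap
#' panel of fixed size and the estimates from the full set of
#' linkage-equilibrium markers, for genomic inbreeding (over individuals)
#' and pairwise kinship (over a pair set).
#'
#' @slot panelSize integer number of SNPs per panel.
#' @slot nReplicates integer number of bootstrap replicates.
#' @slot corInbreeding,corKinship numeric per-replicate correlations
#'   (length 0 when the statistic was not evaluated; NA for a replicate
#'   whose correlation was undefined).
#' @slot withReplacement logical sampling mode.
#' @slot masterSeed integer seed all replicate seeds derive from.
#' @export
setClass("PanelEvaluation",
  representation(
    panelSize       = "integer",
    nReplicates     = "integer",
    corInbreeding   = "numeric",
    corKinship      = "numeric",
    withReplacement = "logical",
    masterSeed      = "integer"
  )
)

#' TruthRecord: simulator-side ground truth
#'
#' Founder-gamete labels per individual and locus from gene dropping,
#' the true pedigree (before any error injection), and per-individual true
#' inbreeding (proportion of loci with two IBD alleles). Realized kinship
#' for any pair is computed on demand with \code{realizedKinship}.
#'
#' @slot labels1,labels2 integer matrices (individuals x loci) of
#'   founder-gamete labels for the paternal and maternal haplotype.
#' @slot truePedigree the generating \linkS4class{Pedigree}.
#' @slot trueInbreeding numeric per-individual proportion of IBD loci.
#' @export
setClass("TruthRecord",
  representation(
    labels1        = "matrix",
    labels2        = "matrix",
    truePedigree   = "Pedigree",
    trueInbreeding = "numeric"
  )
)

setValidity("TruthRecord", function(object) {
  msg <- character()
  if (!identical(dim(object@labels1), dim(object@labels2)))
    msg <- c(msg, "label matrices must have identical dimensions")
  if (length(object@trueInbreeding) != nrow(object@labels1))
    msg <- c(msg, "trueInbreeding must have one entry per individual")
  if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the gene-dropping simulator
#'
#' The generator's defaults describe a multi-generation livestock line:
#' founder minor-allele frequencies at or above the 0.05 QC threshold,
#' autosomes only, Haldane (no-interference) recombination on a
#' centimorgan map, optional perfect-copy founder LD blocks, and optional
#' missingness and recorded-sire errors.
#'
#' @slot nFounders,nGenerations,offspringPerMating integer pedigree shape.
#' @slot matingScheme "random" (pair mating) or "half_sib_heavy" (one sire
#'   per generation mated to every available dam).
#' @slot nChromosomes,snpsPerChromosome integer marker layout.
#' @slot chromosomeLengthCM numeric genetic length per chromosome
#'   (recycled across chromosomes).
#' @slot mafRange numeric length-2, uniform bounds for the coded-allele
#'   founder frequency.
#' @slot ldBlockSnps integer SNPs per founder LD block (1 = linkage
#'   equilibrium founders).
#' @slot missingRate,pedigreeErrorRate numeric probabilities.
#' @slot seed integer master seed; every random sub-stream derives from it.
#' @export
setClass("SimConfig",
  representation(
    nFounders          = "integer",
    nGenerations       = "integer",
    offspringPerMating = "integer",
    matingScheme       = "character",
    nChromosomes       = "integer",
    snpsPerChromosome  = "integer",
    chromosomeLengthCM = "numeric",
    mafRange           = "numeric",
    ldBlockSnps        = "integer",
    missingRate        = "numeric",
    pedigreeErrorRate  = "numeric",
    seed               = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(nFounders = object@nFounders, nGenerations = object@nGenerations,
           offspringPerMating = object@offspringPerMating,
           nChromosomes = object@nChromosomes,
           snpsPerChromosome = object@snpsPerChromosome,
           ldBlockSnps = object@ldBlockSnps)
  if (any(cnt < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (!object@matingScheme %in% c("random", "half_sib_heavy"))
    msg <- c(msg, "matingScheme must be 'random' or 'half_sib_heavy'")
  if (object@nFounders < 2L) msg <- c(msg, "need at least one founder of each sex")
  if (any(object@chromosomeLengthCM < 0)) msg <- c(msg, "chromosome lengths must be >= 0")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange >= 1) || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be increasing bounds inside (0, 1)")
  for (p in c("missingRate", "pedigreeErrorRate")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0, 1]", p))
  }
  if (length(msg)) msg else TRUE
})
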