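#' Accessors for snpkin classes
#'
#' Small, stable accessors so user code never touches slots directly.
#'
#' @param x a snpkin object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("genotypeCodes", function(x) standardGeneric("genotypeCodes"))
#' @rdname accessors
#' @export
setGeneric("lineLabels", function(x) standardGeneric("lineLabels"))
#' @rdname accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))
#' @rdname accessors
#' @export
setGeneric("kinshipValues", function(x) standardGeneric("kinshipValues"))

setMethod("sampleIds", "GenotypeData", function(x) rownames(x@codes))
setMethod("snpIds", "GenotypeData", function(x) colnames(x@codes))
setMethod("genotypeCodes", "GenotypeData", function(x) x@codes)
setMethod("lineLabels", "GenotypeData",
          function(x) setNames(x@line, rownames(x@codes)))
setMethod("markerMap", "GenotypeData", function(x)
  data.frame(chromosome = x@chromosome, snp = colnames(x@codes),
             cM = x@positionCM, bp = x@positionBp,
             codedAllele = x@codedAllele, otherAllele = x@otherAllele,
             row.names = NULL))

setMethod("sampleIds", "Pedigree", function(x) x@id)
setMethod("kinshipValues", "KinshipMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("pedigreeTable", function(x) standardGeneric("pedigreeTable"))
setMethod("pedigreeTable", "Pedigree", function(x)
  data.frame(id = x@id, sire = x@sire, dam = x@dam, sex = x@sex,
             line = x@line, row.names = NULL))

#' Subset a GenotypeData object
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param i sample index (ids, logical or integer).
#' @param j SNP index (ids, logical or integer).
#' @param ... ignored.
#' @param drop ignored; the result is always a GenotypeData.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@codes))
  if (missing(j)) j <- seq_len(ncol(x@codes))
  if (is.character(j)) j <- match(j, colnames(x@codes))
  if (is.character(i)) i <- match(i, rownames(x@codes))
  ii <- seq_len(nrow(x@codes))[i]
  jj <- seq_len(ncol(x@codes))[j]
  new("GenotypeData",
      codes = x@codes[ii, jj, drop = FALSE],
      line = x@line[ii],
      chromosome = x@chromosome[jj],
      positionBp = x@positionBp[jj],
      positionCM = x@positionCM[jj],
      codedAllele = x@codedAllele[jj],
      otherAllele = x@otherAllele[jj])
})

setMethod("dim", "GenotypeData", function(x) dim(x@codes))

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d samples x %d SNPs\n",
              nrow(object@codes), ncol(object@codes)))
  cat(sprintf("  lines: %s\n",
              paste(sprintf("%s (%d)", names(table(object@line)),
                            table(object@line)), collapse = ", ")))
  cat(sprintf("  chromosomes: %d; missing genotypes: %.2f%%\n",
              length(unique(object@chromosome)),
              100 * mean(is.na(object@codes))))
})

setMethod("show", "Pedigree", function(object) {
  nf <- sum(is.na(object@sire) & is.na(object@dam))
  cat(sprintf("Pedigree: %d individuals (%d founders)\n",
              length(object@id), nf))
})

setMethod("show", "KinshipMatrix", function(object) {
  d <- diag(object@values)
  cat(sprintf("KinshipMatrix: %d x %d\n", nrow(object@values), ncol(object@values)))
  cat(sprintf("  genomic inbreeding (2*diag - 1): mean %.3f, sd %.3f\n",
              mean(2 * d - 1), sd(2 * d - 1)))
})

setMethod("show", "QCReport", function(object) {
  cat("QC report (SNPs attributed to the first filter that removed them)\n")
  cat(sprintf("  Mendelian errors : %d SNPs\n", length(object@removedMendel)))
  cat(sprintf("  MAF (per line)   : %d SNPs\n", length(object@removedMaf)))
  cat(sprintf("  call rate        : %d SNPs\n", length(object@removedCallrate)))
  cat(sprintf("  sex chromosomes  : %d SNPs\n", length(object@removedSexchrom)))
  cat(sprintf("  individuals      : %d samples\n", length(object@removedIndividuals)))
  cat(sprintf("  surviving        : %d SNPs x %d samples\n",
              object@survivingSnps, object@survivingSamples))
})

setMethod("show", "PanelEvaluation", function(object) {
  cat(sprintf("PanelEvaluation: %d SNPs, %d replicates (%s replacement)\n",
              object@panelSize, object@nReplicates,
              if (object@withReplacement) "with" else "without"))
  if (length(object@corInbreeding))
    cat(sprintf("  inbreeding r: mean %.3f  min %.3f\n",
                mean(object@corInbreeding, na.rm = TRUE),
                min(object@corInbreeding, na.rm = TRUE)))
  if (length(object@corKinship))
    cat(sprintf("  kinship r   : mean %.3f  min %.3f\n",
                mean(object@corKinship, na.rm = TRUE),
                min(object@corKinship, na.rm = TRUE)))
})

setMethod("show", "TruthRecord", function(object) {
  cat(sprintf("TruthRecord: %d individuals x %d loci; mean true F = %.4f\n",
              nrow(object@labels1), ncol(object@labels1),
              mean(object@trueInbreeding)))
})

#' Summary statistics of bootstrap panel correlations
#'
#' Mean, median, quartiles, extremes and the coefficient of variation
#' (SD/mean) of the per-replicate correlations, for each statistic that was
#' evaluated. Quartiles use linear interpolation. Replicates with an
#' undefined correlation are excluded and counted.
#'
#' @param object a \linkS4class{PanelEvaluation}.
#' @param ... ignored.
#' @return a data.frame with one row per statistic.
#' @export
setMethod("summary", "PanelEvaluation", function(object, ...) {
  one <- function(r, what) {
    r0 <- r[!is.na(r)]
    data.frame(statistic = what, panelSize = object@panelSize,
               n = length(r0), nUndefined = sum(is.na(r)),
               mean = mean(r0), median = median(r0),
               q1 = unname(quantile(r0, 0.25)), q3 = unname(quantile(r0, 0.75)),
               min = min(r0), max = max(r0), cv = sd(r0) / mean(r0))
  }
  out <- list()
  if (length(object@corInbreeding))
    out$inb <- one(object@corInbreeding, "inbreeding")
  if (length(object@corKinship))
    out$kin <- one(object@corKinship, "kinship")
  do.call(rbind, out)
})
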