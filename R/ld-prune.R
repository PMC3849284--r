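#' Squared correlation (r^2) between two SNPs' genotype codes
#'
#' Composite (genotypic) linkage disequilibrium: the squared Pearson
#' correlation of genotype codes over pairwise-complete samples. A vector
#' monomorphic among the complete pairs has undefined r^2, which is
#' treated as 0 (nothing to prune on).
#'
#' @param a,b numeric genotype-code vectors of equal length.
#' @return r^2 in [0, 1].
#' @export
snpR2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(0)
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) return(0)
  cor(a[ok], b[ok])^2
}

#' Prune one chromosome's SNPs by windowed pairwise r^2
#'
#' A window of \code{windowSnps} consecutive positions of the sorted SNP
#' list is examined; among the currently kept SNPs in the window, while
#' any pair has r^2 above \code{r2Max}, one member of the first offending
#' pair is removed (the lower-MAF member; on a tie, the later SNP in map
#' order). The window then shifts \code{stepSnps} positions forward until
#' the end of the chromosome. Windows index the original sorted SNP list;
#' removed SNPs are skipped when forming pairs. In the returned set, no
#' pair that ever co-occurred in a window exceeds the threshold, so
#' re-running the pruner on its own output removes nothing.
#'
#' @param codes samples x SNPs matrix for one chromosome, columns in map
#'   order.
#' @param windowSnps,stepSnps,r2Max pruning parameters (defaults 50, 5,
#'   0.5).
#' @return character vector of kept SNP ids (columns of \code{codes}).
#' @export
pruneChromosome <- function(codes, windowSnps = 50, stepSnps = 5, r2Max = 0.5) {
  stopifnot(windowSnps >= 2, stepSnps >= 1, stepSnps <= windowSnps,
            r2Max > 0, r2Max < 1)
  m <- ncol(codes)
  if (m < 2) return(colnames(codes))
  p <- colMeans(codes, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, m)
  starts <- seq(1, m, by = stepSnps)
  for (s in starts) {
    win <- s:min(s + windowSnps - 1, m)
    idx <- win[keep[win]]
    if (length(idx) < 2) next
    R <- suppressWarnings(cor(codes[, idx, drop = FALSE],
                              use = "pairwise.complete.obs"))^2
    R[is.na(R)] <- 0
    diag(R) <- 0
    repeat {
      off <- which(R > r2Max, arr.ind = TRUE)
      off <- off[off[, 1] < off[, 2], , drop = FALSE]
      if (nrow(off) == 0) break
      # first offending pair in column-major upper-triangle order
      o <- off[order(off[, 2], off[, 1])[1], ]
      i <- idx[o[1]]; j <- idx[o[2]]
      drop <- if (maf[i] < maf[j]) o[1] else if (maf[j] < maf[i]) o[2] else o[2]
      keep[idx[drop]] <- FALSE
      R[drop, ] <- 0
      R[, drop] <- 0
    }
  }
  colnames(codes)[keep]
}

#' Select the linkage-equilibrium marker set per line
#'
#' Runs \code{\link{pruneChromosome}} on every chromosome, within every
#' line (allele frequencies, and therefore LD, differ between lines), and
#' summarizes kept counts and mean inter-marker spacing.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param windowSnps,stepSnps,r2Max pruning parameters.
#' @param byLine prune within each line separately (default) or on the
#'   pooled sample.
#' @return list with \code{keep} (per line: character vector of kept SNP
#'   ids, in map order), \code{common} (ids kept in every line) and
#'   \code{summary} (per line x chromosome: total, kept, proportion, mean
#'   spacing in Mb, computed as (max bp - min bp)/(kept - 1)).
#' @export
pruneAll <- function(genotypes, windowSnps = 50, stepSnps = 5, r2Max = 0.5,
                     byLine = TRUE) {
  lines <- if (byLine) unique(genotypes@line) else "all"
  keep <- list()
  summ <- list()
  for (ln in lines) {
    g <- if (byLine) genotypes[genotypes@line == ln, ] else genotypes
    codes <- genotypeCodes(g)
    keptIds <- character(0)
    for (ch in unique(g@chromosome)) {
      jj <- which(g@chromosome == ch)
      ids <- pruneChromosome(codes[, jj, drop = FALSE],
                             windowSnps, stepSnps, r2Max)
      keptIds <- c(keptIds, ids)
      bp <- g@positionBp[jj][match(ids, colnames(codes)[jj])]
      summ[[length(summ) + 1L]] <- data.frame(
        line = ln, chromosome = ch, nTotal = length(jj),
        nKept = length(ids), propKept = length(ids) / length(jj),
        spacingMb = if (length(ids) > 1)
          (max(bp) - min(bp)) / (length(ids) - 1) / 1e6 else NA_real_)
    }
    keep[[ln]] <- keptIds
  }
  list(keep = keep,
       common = Reduce(intersect, keep),
       summary = do.call(rbind, summ))
}
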