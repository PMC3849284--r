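#' Chromosome-proportional allocation of panel SNP counts
#'
#' Allocates a panel of \code{panelSize} SNPs across chromosomes in
#' proportion to the number of linkage-equilibrium markers each one
#' carries, so chromosomes with more available markers contribute more to
#' the reduced panel. Rounding uses the largest-remainder method, which
#' sums exactly to \code{panelSize} (ties broken toward the earlier
#' chromosome).
#'
#' @param panelSize total SNPs in the panel.
#' @param leCounts named integer vector: LE markers available per
#'   chromosome.
#' @param withReplacement if FALSE, a chromosome is never allocated more
#'   SNPs than it has (the excess is redistributed), and the panel must
#'   not exceed the total LE count.
#' @return integer vector of per-chromosome counts, same names as
#'   \code{leCounts}.
#' @export
allocatePanelCounts <- function(panelSize, leCounts, withReplacement = TRUE) {
  stopifnot(panelSize >= 1, sum(leCounts) >= 1)
  if (!withReplacement && panelSize > sum(leCounts))
    stop("panel larger than the LE set cannot be sampled without replacement")
  q <- panelSize * leCounts / sum(leCounts)
  counts <- floor(q)
  rem <- q - counts
  short <- panelSize - sum(counts)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  if (!withReplacement) {
    while (any(over <- counts > leCounts)) {
      excess <- sum(counts[over] - leCounts[over])
      counts[over] <- leCounts[over]
      room <- which(counts < leCounts)
      add <- room[order(rem[room], decreasing = TRUE)]
      for (k in add) {
        if (excess == 0) break
        inc <- min(excess, leCounts[k] - counts[k])
        counts[k] <- counts[k] + inc
        excess <- excess - inc
      }
    }
  }
  stats::setNames(as.integer(counts), names(leCounts))
}

#' Sample one bootstrap panel of SNPs
#'
#' Uniform sampling of the allocated count within each chromosome, with
#' replacement by default (duplicated SNPs act with multiplicity in
#' downstream averages). Deterministic given the seed.
#'
#' @param leByChrom list of character vectors: LE SNP ids per chromosome.
#' @param counts per-chromosome counts from
#'   \code{\link{allocatePanelCounts}} (same order).
#' @param withReplacement logical.
#' @param seed integer seed.
#' @return character vector (multiset) of sampled SNP ids.
#' @export
samplePanel <- function(leByChrom, counts, withReplacement = TRUE, seed = 1) {
  stopifnot(length(leByChrom) == length(counts))
  set.seed(seed)
  unlist(lapply(seq_along(leByChrom), function(ch) {
    pool <- leByChrom[[ch]]
    if (counts[ch] == 0) return(character(0))
    pool[sample.int(length(pool), counts[ch], replace = withReplacement)]
  }), use.names = FALSE)
}

# replicate seed derived from the master seed, panel-size index and
# replicate number; kept inside 32-bit integer range
.replicateSeed <- function(masterSeed, sizeIndex, replicate) {
  as.integer((as.numeric(masterSeed) + 1664525 * sizeIndex +
                1013904223 * replicate) %% 2147483647)
}

#' Bootstrap evaluation of reduced SNP panels
#'
#' For each panel size and bootstrap replicate: sample a
#' chromosome-weighted panel from the linkage-equilibrium set, re-estimate
#' genomic inbreeding and/or pairwise kinship from the panel (allele
#' frequencies inherited from the full-set estimates; duplicated SNPs
#' counted with multiplicity), and record the Pearson correlation with the
#' full-LE-set estimates over individuals (inbreeding) and over the pair
#' set (kinship). A replicate with an undefined correlation
#' (zero-variance vector) is stored as NA and excluded from summaries.
#'
#' @param genotypes a \linkS4class{GenotypeData} (typically one line,
#'   post-QC).
#' @param leSet character vector of LE SNP ids (from
#'   \code{\link{pruneAll}}).
#' @param sizes panel sizes (default the study grid 500...3000).
#' @param nReplicates bootstrap replicates per size (default 1000).
#' @param statistic which agreement to evaluate.
#' @param pairs two-column matrix of ids for the kinship correlation;
#'   NULL means all unordered pairs of evaluated individuals.
#' @param freq coded-allele frequencies; NULL uses sample frequencies of
#'   \code{genotypes} (computed once and shared by the full set and every
#'   panel).
#' @param withReplacement bootstrap mode (default TRUE, the study's
#'   procedure).
#' @param masterSeed integer; replicate seeds derive deterministically
#'   from it.
#' @return list of \linkS4class{PanelEvaluation}, one per size, named by
#'   size.
#' @export
evaluatePanels <- function(genotypes, leSet,
                           sizes = c(500, 1000, 1500, 2000, 2500, 3000),
                           nReplicates = 1000,
                           statistic = c("both", "inbreeding", "kinship"),
                           pairs = NULL, freq = NULL,
                           withReplacement = TRUE, masterSeed = 1) {
  statistic <- match.arg(statistic)
  doInb <- statistic %in% c("both", "inbreeding")
  doKin <- statistic %in% c("both", "kinship")
  le <- genotypes[, leSet]
  if (is.null(freq)) freq <- alleleFrequencies(le)
  p <- setNames(.matchFreq(freq, snpIds(le)), snpIds(le))
  leByChrom <- split(snpIds(le), le@chromosome)
  leCounts <- lengths(leByChrom)

  fullInb <- if (doInb) genomicInbreeding(le, freq = p) else NULL
  pairIdx <- NULL
  fullKinPairs <- NULL
  if (doKin) {
    K <- genomicKinship(le, freq = p)
    if (is.null(pairs)) {
      ut <- which(upper.tri(K@values), arr.ind = TRUE)
      ids <- rownames(K@values)
      pairs <- cbind(ids[ut[, 1]], ids[ut[, 2]])
    }
    pairs <- as.matrix(pairs)
    pairIdx <- cbind(match(pairs[, 1], rownames(K@values)),
                     match(pairs[, 2], rownames(K@values)))
    fullKinPairs <- K@values[pairIdx]
  }

  out <- list()
  for (si in seq_along(sizes)) {
    size <- sizes[si]
    counts <- allocatePanelCounts(size, leCounts, withReplacement)
    rInb <- if (doInb) rep(NA_real_, nReplicates) else numeric(0)
    rKin <- if (doKin) rep(NA_real_, nReplicates) else numeric(0)
    for (r in seq_len(nReplicates)) {
      panel <- samplePanel(leByChrom, counts, withReplacement,
                           seed = .replicateSeed(masterSeed, si, r))
      w <- table(factor(panel, levels = snpIds(le)))
      nz <- which(w > 0)
      wts <- as.numeric(w[nz])
      if (doInb) {
        fi <- genomicInbreeding(le, freq = p[nz], snps = nz, weights = wts)
        if (sd(fi) > 0 && sd(fullInb) > 0) rInb[r] <- cor(fi, fullInb)
      }
      if (doKin) {
        Kp <- genomicKinship(le, freq = p[nz], snps = nz, weights = wts)
        v <- Kp@values[pairIdx]
        if (sd(v) > 0 && sd(fullKinPairs) > 0) rKin[r] <- cor(v, fullKinPairs)
      }
    }
    nUndef <- sum(is.na(rInb)) + sum(is.na(rKin))
    if (nUndef > 0)
      message(sprintf("panel size %d: %d replicate correlation(s) undefined, excluded",
                      size, nUndef))
    out[[as.character(size)]] <- new("PanelEvaluation",
                                     panelSize = as.integer(size),
                                     nReplicates = as.integer(nReplicates),
                                     corInbreeding = rInb,
                                     corKinship = rKin,
                                     withReplacement = withReplacement,
                                     masterSeed = as.integer(masterSeed))
  }
  out
}
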