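#' Extract relationship pair classes from a pedigree
#'
#' Father-offspring pairs are the recorded sire-offspring pairs (optionally
#' restricted to those whose paternity was confirmed); full sibs share both
#' (known) parents; half sibs share exactly one known parent. Classes are
#' disjoint: a pair that is also parent-offspring (possible under
#' consanguineous matings) stays in the father-offspring class only.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param samples optional ids restricting every class (e.g. the genotyped
#'   individuals of one line).
#' @param paternity optional result of \code{\link{checkPaternity}}; only
#'   pairs with verdict "confirmed" enter the father-offspring class.
#' @return list of two-column matrices: \code{fatherOffspring},
#'   \code{fullSibs}, \code{halfSibs}.
#' @export
extractPairClasses <- function(pedigree, samples = NULL, paternity = NULL) {
  id <- pedigree@id
  if (is.null(samples)) samples <- id
  ok <- !is.na(pedigree@sire) & pedigree@sire %in% samples & id %in% samples
  fo <- cbind(pedigree@sire[ok], id[ok])
  if (!is.null(paternity)) {
    conf <- paste(paternity$sire, paternity$offspring)[paternity$verdict == "confirmed"]
    fo <- fo[paste(fo[, 1], fo[, 2]) %in% conf, , drop = FALSE]
  }
  inSet <- id %in% samples
  sire <- pedigree@sire; dam <- pedigree@dam
  rank <- setNames(seq_along(id), id)
  # all within-group unordered pairs, canonically ordered by pedigree rank
  groupPairs <- function(parent) {
    cand <- which(inSet & !is.na(parent))
    keys <- character(0)
    for (g in split(id[cand], parent[cand])) {
      if (length(g) < 2) next
      pr <- utils::combn(g, 2)
      swap <- rank[pr[1, ]] > rank[pr[2, ]]
      keys <- c(keys, ifelse(swap, paste(pr[2, ], pr[1, ]),
                             paste(pr[1, ], pr[2, ])))
    }
    keys
  }
  sirePairs <- groupPairs(sire)
  damPairs <- groupPairs(dam)
  fsKeys <- intersect(sirePairs, damPairs)            # share both parents
  hsKeys <- setdiff(union(sirePairs, damPairs), fsKeys)  # share exactly one
  toMat <- function(keys) if (length(keys))
    matrix(unlist(strsplit(keys, " ", fixed = TRUE)), ncol = 2, byrow = TRUE)
  else matrix(character(0), ncol = 2)
  fsM <- toMat(fsKeys); hsM <- toMat(hsKeys)
  # keep classes disjoint from father-offspring (priority to the FO class)
  foKey <- c(paste(fo[, 1], fo[, 2]), paste(fo[, 2], fo[, 1]))
  fsM <- fsM[!(paste(fsM[, 1], fsM[, 2]) %in% foKey), , drop = FALSE]
  hsM <- hsM[!(paste(hsM[, 1], hsM[, 2]) %in% foKey), , drop = FALSE]
  list(fatherOffspring = fo, fullSibs = fsM, halfSibs = hsM)
}

#' Per-class summaries and estimator correlations
#'
#' The study's comparison surface: for each pair class (and the whole
#' population, i.e. all unordered pairs of the evaluated individuals) and
#' each kinship estimator, n, mean, SD, min and max; plus the Pearson
#' correlation between every pair of estimators within each class. A class
#' with fewer than 3 pairs has its correlations withheld (NA).
#'
#' @param estimators named list of kinship sources, each either a
#'   \linkS4class{KinshipMatrix} or a plain symmetric matrix with id
#'   dimnames (e.g. \code{aMatrix(ped)/2} for pedigree kinship).
#' @param classes list of pair matrices from
#'   \code{\link{extractPairClasses}}.
#' @param samples ids defining the all-pairs population class; NULL skips
#'   that class.
#' @return list with \code{summary} (data.frame: class, estimator, n,
#'   mean, sd, min, max) and \code{correlations} (data.frame: class,
#'   estimator1, estimator2, r, n).
#' @export
summarizeAndCorrelate <- function(estimators, classes, samples = NULL) {
  getVals <- function(est, pairs) {
    m <- if (is(est, "KinshipMatrix")) est@values else est
    i <- match(pairs[, 1], rownames(m)); j <- match(pairs[, 2], colnames(m))
    if (anyNA(i) || anyNA(j)) stop("pair ids missing from an estimator")
    m[cbind(i, j)]
  }
  if (!is.null(samples)) {
    n <- length(samples)
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    classes <- c(classes, list(allPairs = cbind(samples[ut[, 1]],
                                                samples[ut[, 2]])))
  }
  summ <- list(); corr <- list()
  for (cl in names(classes)) {
    pairs <- classes[[cl]]
    vals <- lapply(estimators, getVals, pairs = pairs)
    for (e in names(vals)) {
      v <- vals[[e]]
      summ[[length(summ) + 1L]] <- data.frame(
        class = cl, estimator = e, n = nrow(pairs),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) sd(v) else NA_real_,
        min = if (length(v)) min(v) else NA_real_,
        max = if (length(v)) max(v) else NA_real_)
    }
    es <- names(vals)
    for (a in seq_along(es)) for (b in seq_len(a - 1L)) {
      r <- if (nrow(pairs) >= 3) {
        va <- vals[[es[a]]]; vb <- vals[[es[b]]]
        if (sd(va) > 0 && sd(vb) > 0) cor(va, vb) else NA_real_
      } else NA_real_
      corr[[length(corr) + 1L]] <- data.frame(
        class = cl, estimator1 = es[b], estimator2 = es[a],
        r = r, n = nrow(pairs))
    }
  }
  list(summary = do.call(rbind, summ), correlations = do.call(rbind, corr))
}

#' Inbreeding summary table across estimators
#'
#' Mean, SD, min and max of per-individual inbreeding for each estimator
#' (e.g. pedigree, all markers, LE markers), per line, plus pairwise
#' Pearson correlations between estimators within line.
#'
#' @param estimates named list of named numeric vectors (id -> F).
#' @param line optional named factor/character (id -> line); NULL treats
#'   everything as one line.
#' @return list with \code{summary} and \code{correlations} data.frames.
#' @export
inbreedingTable <- function(estimates, line = NULL) {
  ids <- Reduce(intersect, lapply(estimates, names))
  if (is.null(line)) line <- setNames(rep("all", length(ids)), ids)
  summ <- list(); corr <- list()
  for (ln in unique(line[ids])) {
    sel <- ids[line[ids] == ln]
    for (e in names(estimates)) {
      v <- estimates[[e]][sel]
      summ[[length(summ) + 1L]] <- data.frame(
        line = ln, estimator = e, n = length(v), mean = mean(v),
        sd = sd(v), min = min(v), max = max(v))
    }
    es <- names(estimates)
    for (a in seq_along(es)) for (b in seq_len(a - 1L)) {
      corr[[length(corr) + 1L]] <- data.frame(
        line = ln, estimator1 = es[b], estimator2 = es[a],
        r = cor(estimates[[es[b]]][sel], estimates[[es[a]]][sel]))
    }
  }
  list(summary = do.call(rbind, summ), correlations = do.call(rbind, corr))
}
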