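#' Construct a Pedigree
#'
#' @param id character individual ids (unique).
#' @param sire,dam parent ids; \code{NA} or \code{"0"} for unknown.
#' @param sex "M"/"F"/NA, or PLINK codes 1 (male), 2 (female), 0 (unknown).
#' @param line line label per individual (single value recycled).
#' @return a validated \linkS4class{Pedigree}.
#' @export
Pedigree <- function(id, sire = NA, dam = NA, sex = NA, line = "L1") {
  id <- as.character(id)
  n <- length(id)
  norm <- function(x) {
    x <- as.character(rep_len(x, n)); x[x %in% c("0", "")] <- NA; x
  }
  sx <- as.character(rep_len(sex, n))
  sx[sx == "1"] <- "M"; sx[sx == "2"] <- "F"
  sx[!sx %in% c("M", "F")] <- NA
  new("Pedigree", id = id, sire = norm(sire), dam = norm(dam),
      sex = sx, line = as.character(rep_len(line, n)))
}

#' Topological order of a pedigree
#'
#' Kahn's algorithm over the parent-offspring relation. Errors (naming one
#' offending id) if the pedigree contains a cycle.
#'
#' @param ped a \linkS4class{Pedigree} (validity not yet required, so this
#'   can run inside the validity method itself).
#' @return integer permutation such that every parent precedes its offspring.
#' @export
topoOrder <- function(ped) {
  id <- ped@id
  n <- length(id)
  si <- match(ped@sire, id)
  di <- match(ped@dam, id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in c(si[j], di[j])) {
      if (!is.na(p)) {
        indeg[j] <- indeg[j] + 1L
        kids[[p]] <- c(kids[[p]], j)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    bad <- id[setdiff(seq_len(n), ord)][1]
    stop(sprintf("pedigree contains a cycle involving id '%s'", bad))
  }
  ord
}

# parent indices after reordering the pedigree topologically; used by the
# pedigree-kinship algorithms, which require parents before offspring.
.pedIndices <- function(ped) {
  ord <- topoOrder(ped)
  id <- ped@id[ord]
  list(id = id,
       sire = match(ped@sire[ord], id),
       dam  = match(ped@dam[ord], id),
       order = ord)
}

#' Read a pedigree file
#'
#' Tab- (or white-space-) separated columns id, sire, dam, sex, line; "0"
#' marks an unknown parent. Parents that appear only in a parent column are
#' added as founder records (with a message). Offspring may precede their
#' parents in the file; a topological order is computed internally.
#'
#' @param path file path.
#' @return a \linkS4class{Pedigree}.
#' @export
readPedigree <- function(path) {
  df <- data.table::fread(path, header = FALSE, colClasses = "character",
                          data.table = FALSE)
  if (ncol(df) < 3) stop("pedigree file needs at least id, sire, dam columns")
  names(df)[1:3] <- c("id", "sire", "dam")
  sex <- if (ncol(df) >= 4) df[[4]] else NA
  line <- if (ncol(df) >= 5) df[[5]] else "L1"
  sire <- df$sire; dam <- df$dam
  sire[sire == "0"] <- NA; dam[dam == "0"] <- NA
  extraSires <- setdiff(sire, c(df$id, NA))
  extraDams <- setdiff(dam, c(df$id, NA))
  if (length(extraSires) || length(extraDams)) {
    message(sprintf("adding %d implicit founder record(s) for parents not defined in the file",
                    length(extraSires) + length(extraDams)))
  }
  Pedigree(
    id   = c(df$id, extraSires, extraDams),
    sire = c(sire, rep(NA, length(extraSires) + length(extraDams))),
    dam  = c(dam, rep(NA, length(extraSires) + length(extraDams))),
    sex  = c(sex, rep("M", length(extraSires)), rep("F", length(extraDams))),
    line = c(line, rep(line[1], length(extraSires) + length(extraDams)))
  )
}

#' Write a pedigree file
#'
#' Tab-separated id, sire, dam, sex, line with "0" for unknown parents, the
#' inverse of \code{\link{readPedigree}}.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param path output file path.
#' @export
writePedigree <- function(ped, path) {
  df <- pedigreeTable(ped)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  df$sex[is.na(df$sex)] <- "0"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
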