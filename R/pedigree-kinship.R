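#' Pedigree inbreeding by the Meuwissen-Luo recursion
#'
#' Computes F_i = a_ii - 1 from the L D L' decomposition of the numerator
#' relationship matrix without ever forming the matrix: for each
#' individual, its ancestor contributions L are accumulated from child to
#' parents (halving at each step) and combined with the within-family
#' variances D_j = 0.5 - 0.25 (F_sire + F_dam), where an unknown parent
#' contributes F = -1 to D. Founders and individuals with any unknown
#' parent have F = 0 (unknown parents are taken as unrelated, non-inbred
#' founders).
#'
#' @param pedigree a \linkS4class{Pedigree} (any record order; a
#'   topological order is computed internally).
#' @return named numeric vector of inbreeding coefficients in [0, 1).
#' @export
pedigreeInbreeding <- function(pedigree) {
  idx <- .pedIndices(pedigree)
  n <- length(idx$id)
  s <- idx$sire; d <- idx$dam
  FF <- numeric(n)
  D <- numeric(n)
  for (j in seq_len(n)) {
    fs <- if (is.na(s[j])) -1 else FF[s[j]]
    fd <- if (is.na(d[j])) -1 else FF[d[j]]
    D[j] <- 0.5 - 0.25 * (fs + fd)
    if (is.na(s[j]) || is.na(d[j])) { FF[j] <- 0; next }
    L <- numeric(j)
    L[j] <- 1
    a <- 0
    for (k in j:1) {
      if (L[k] == 0) next
      a <- a + L[k]^2 * D[k]
      if (!is.na(s[k])) L[s[k]] <- L[s[k]] + L[k] / 2
      if (!is.na(d[k])) L[d[k]] <- L[d[k]] + L[k] / 2
    }
    FF[j] <- a - 1
  }
  setNames(FF, idx$id)[pedigree@id]
}

#' Numerator relationship matrix by the tabular method
#'
#' a_jj = 1 + a(sire_j, dam_j)/2 and a_ij = (a(i, sire_j) + a(i, dam_j))/2
#' for i earlier than j, with unknown parents contributing 0. Kinship
#' (co-ancestry) is half the relationship: phi = A/2, so the diagonal is
#' 1 + F and founders sit at exactly 1.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @return symmetric numeric matrix with individual ids as dimnames, in
#'   the original pedigree record order.
#' @export
aMatrix <- function(pedigree) {
  idx <- .pedIndices(pedigree)
  n <- length(idx$id)
  s <- idx$sire; d <- idx$dam
  A <- matrix(0, n, n, dimnames = list(idx$id, idx$id))
  for (j in seq_len(n)) {
    as_ <- if (is.na(s[j])) numeric(n) else A[, s[j]]
    ad <- if (is.na(d[j])) numeric(n) else A[, d[j]]
    col <- (as_ + ad) / 2
    if (j > 1) {
      A[seq_len(j - 1), j] <- col[seq_len(j - 1)]
      A[j, seq_len(j - 1)] <- col[seq_len(j - 1)]
    }
    A[j, j] <- 1 + (if (is.na(s[j]) || is.na(d[j])) 0 else A[s[j], d[j]] / 2)
  }
  back <- match(pedigree@id, idx$id)
  A[back, back, drop = FALSE]
}

#' Recursive kinship oracle
#'
#' Direct memoized recursion on the co-ancestry definition, independent of
#' the tabular and Meuwissen-Luo implementations and used to cross-check
#' them: phi(i, i) = (1 + phi(sire_i, dam_i)) / 2 and, taking i as the
#' individual later in topological order, phi(i, j) = (phi(sire_i, j) +
#' phi(dam_i, j)) / 2; unknown-parent terms are 0.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param i,j individual ids.
#' @return the kinship coefficient phi(i, j).
#' @export
recursiveKinship <- function(pedigree, i, j) {
  idx <- .pedIndices(pedigree)
  rank <- setNames(seq_along(idx$id), idx$id)
  memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    if (rank[[a]] < rank[[b]]) { tmp <- a; a <- b; b <- tmp }
    key <- paste(a, b)
    if (!is.null(memo[[key]])) return(memo[[key]])
    ia <- rank[[a]]
    sa <- idx$sire[ia]; da <- idx$dam[ia]
    sid <- if (is.na(sa)) NA_character_ else idx$id[sa]
    did <- if (is.na(da)) NA_character_ else idx$id[da]
    val <- if (a == b) {
      (1 + phi(sid, did)) / 2
    } else {
      (phi(sid, b) + phi(did, b)) / 2
    }
    memo[[key]] <- val
    val
  }
  phi(as.character(i), as.character(j))
}
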