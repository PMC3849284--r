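#' Configure the gene-dropping simulator
#'
#' Builds a validated \linkS4class{SimConfig}. Defaults describe a single
#' closed line genotyped on a medium-density chip after quality control:
#' 18 autosomes of 100 cM carrying equally spaced SNPs, founder
#' coded-allele frequencies uniform on [0.1, 0.5] (safely above the 0.05
#' MAF filter), linkage-equilibrium founders, no missingness and no
#' recorded-pedigree errors.
#'
#' @param nFounders number of generation-0 individuals (sexes alternate
#'   male, female, male, ...).
#' @param nGenerations number of bred generations after the founders.
#' @param offspringPerMating litter size per mating.
#' @param matingScheme "random" mates the previous generation's males and
#'   females in seeded random pairs; "half_sib_heavy" mates a single sire
#'   to every available dam, producing large half-sib families.
#' @param nChromosomes,snpsPerChromosome marker layout.
#' @param chromosomeLengthCM genetic length per chromosome in centimorgan
#'   (recycled); 0 disables recombination on that chromosome.
#' @param mafRange uniform bounds for founder coded-allele frequencies.
#' @param ldBlockSnps SNPs per founder LD block; within a block every SNP
#'   is a perfect copy of one underlying locus (pairwise r^2 = 1 among
#'   founders), blocks are mutually independent. 1 gives LE founders.
#' @param missingRate per-genotype missingness probability.
#' @param pedigreeErrorRate probability that an offspring's recorded sire
#'   is replaced by another male in the written pedigree.
#' @param seed master seed; all random sub-streams derive from it.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nFounders = 16, nGenerations = 5, offspringPerMating = 4,
                      matingScheme = c("random", "half_sib_heavy"),
                      nChromosomes = 18, snpsPerChromosome = 580,
                      chromosomeLengthCM = 100, mafRange = c(0.1, 0.5),
                      ldBlockSnps = 1, missingRate = 0,
                      pedigreeErrorRate = 0, seed = 1) {
  new("SimConfig",
      nFounders = as.integer(nFounders),
      nGenerations = as.integer(nGenerations),
      offspringPerMating = as.integer(offspringPerMating),
      matingScheme = match.arg(matingScheme),
      nChromosomes = as.integer(nChromosomes),
      snpsPerChromosome = as.integer(snpsPerChromosome),
      chromosomeLengthCM = rep_len(as.numeric(chromosomeLengthCM),
                                   as.integer(nChromosomes)),
      mafRange = as.numeric(mafRange),
      ldBlockSnps = as.integer(ldBlockSnps),
      missingRate = as.numeric(missingRate),
      pedigreeErrorRate = as.numeric(pedigreeErrorRate),
      seed = as.integer(seed))
}

# derive a sub-stream seed from the master seed; offsets keep results
# distinct per stage while staying below 2^31
.subSeed <- function(seed, k) as.integer((as.numeric(seed) %% 1e9) + k * 7919)

#' Build a multi-generation pedigree
#'
#' Generation g individuals always have both parents in generation g - 1;
#' founders (generation 0) have unknown parents. Sexes alternate
#' deterministically within every generation, so both father-offspring and
#' (for \code{offspringPerMating > 1}) full-sib and half-sib pairs exist.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{Pedigree} in generation order.
#' @export
buildPedigree <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  nF <- config@nFounders
  id <- sprintf("G0_%04d", seq_len(nF))
  sex <- rep_len(c("M", "F"), nF)
  sire <- rep(NA_character_, nF)
  dam <- rep(NA_character_, nF)
  prevIds <- id; prevSex <- sex
  set.seed(.subSeed(config@seed, 1))
  for (g in seq_len(config@nGenerations)) {
    males <- prevIds[prevSex == "M"]
    females <- prevIds[prevSex == "F"]
    if (!length(males) || !length(females))
      stop(sprintf("generation %d has no available %s; mating impossible",
                   g - 1, if (!length(males)) "sire" else "dam"))
    if (config@matingScheme == "half_sib_heavy") {
      sires <- rep(males[1], length(females))
      dams <- females
    } else {
      nm <- min(length(males), length(females))
      sires <- sample(males)[seq_len(nm)]
      dams <- sample(females)[seq_len(nm)]
    }
    nOff <- length(sires) * config@offspringPerMating
    offId <- sprintf("G%d_%04d", g, seq_len(nOff))
    id <- c(id, offId)
    sire <- c(sire, rep(sires, each = config@offspringPerMating))
    dam <- c(dam, rep(dams, each = config@offspringPerMating))
    offSex <- rep_len(c("M", "F"), nOff)
    sex <- c(sex, offSex)
    prevIds <- offId; prevSex <- offSex
  }
  Pedigree(id = id, sire = sire, dam = dam, sex = sex, line = "L1")
}

#' Simulate founder haplotypes, marker map and allele frequencies
#'
#' Each underlying locus draws its coded-allele frequency from the
#' configured uniform range; founder gametes draw alleles independently at
#' that frequency. With \code{ldBlockSnps > 1}, consecutive SNPs within a
#' chromosome form blocks whose members are exact copies of the block's
#' underlying locus, giving r^2 = 1 among founders within a block and
#' independence between blocks. Physical positions are 1-based, strictly
#' increasing within chromosome (100 kb spacing); genetic positions spread
#' evenly over the chromosome's cM length.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{haplotypes} (2*nFounders x nSnps 0/1 matrix,
#'   rows are founder gametes), \code{freq} (true coded-allele frequency
#'   per SNP) and \code{map} (chromosome, snp, cM, bp).
#' @export
simulateFounders <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(.subSeed(config@seed, 2))
  nGam <- 2L * config@nFounders
  maps <- vector("list", config@nChromosomes)
  haps <- vector("list", config@nChromosomes)
  freqs <- vector("list", config@nChromosomes)
  for (ch in seq_len(config@nChromosomes)) {
    m <- config@snpsPerChromosome
    nBlocks <- ceiling(m / config@ldBlockSnps)
    blockOf <- rep(seq_len(nBlocks), each = config@ldBlockSnps)[seq_len(m)]
    pBlock <- runif(nBlocks, config@mafRange[1], config@mafRange[2])
    hBlock <- matrix(rbinom(nGam * nBlocks, 1L, rep(pBlock, each = nGam)),
                     nrow = nGam, ncol = nBlocks)
    haps[[ch]] <- hBlock[, blockOf, drop = FALSE]
    freqs[[ch]] <- pBlock[blockOf]
    len <- config@chromosomeLengthCM[ch]
    cm <- if (m == 1) len / 2 else seq(0, len, length.out = m)
    maps[[ch]] <- cm
  }
  m <- config@snpsPerChromosome
  map <- data.frame(
    chromosome = rep(seq_len(config@nChromosomes), each = m),
    snp = sprintf("c%d_s%d", rep(seq_len(config@nChromosomes), each = m),
                  rep.int(seq_len(m), config@nChromosomes)),
    cM = unlist(maps),
    bp = rep(as.integer(seq(1L, by = 100000L, length.out = m)),
             config@nChromosomes))
  list(haplotypes = do.call(cbind, haps),
       freq = unlist(freqs),
       map = map)
}

# transmit one recombinant gamete: lab1/lab2 are the parent's two label
# vectors; Haldane model, crossovers Poisson on the cM map, no interference
.dropGamete <- function(lab1, lab2, chromIndex, chromCM, chromLen) {
  nChrom <- length(chromIndex)
  starts <- sample.int(2L, nChrom, replace = TRUE) - 1L
  nxo <- rpois(nChrom, chromLen / 100)
  ph <- rep.int(starts, lengths(chromIndex))
  for (ch in which(nxo > 0L)) {
    xo <- sort(runif(nxo[ch], 0, chromLen[ch]))
    ph[chromIndex[[ch]]] <- (starts[ch] + findInterval(chromCM[[ch]], xo)) %% 2L
  }
  out <- lab1
  sw <- ph == 1L
  out[sw] <- lab2[sw]
  out
}

#' Gene-drop genotypes down a pedigree with IBD tracking
#'
#' Founders' two haplotypes receive unique gamete labels; each offspring
#' receives one recombinant gamete per parent (crossovers as a Poisson
#' process on the cM map, no interference). Labels propagate with the
#' alleles, so realized identity-by-descent is known exactly.
#'
#' @param pedigree a \linkS4class{Pedigree} whose founders (both parents
#'   unknown) match the founder haplotypes; all non-founders must have both
#'   parents in the pedigree.
#' @param founders output of \code{\link{simulateFounders}}.
#' @param seed integer seed for the Mendelian sampling stream.
#' @return list with \code{genotypes} (a \linkS4class{GenotypeData}) and
#'   \code{truth} (a \linkS4class{TruthRecord}).
#' @export
geneDrop <- function(pedigree, founders, seed = 1) {
  map <- founders$map
  if (is.null(map$cM) || anyNA(map$cM))
    stop("marker map lacks cM coordinates; recombination cannot be placed")
  idx <- .pedIndices(pedigree)
  n <- length(idx$id)
  L <- nrow(map)
  fndRow <- which(is.na(idx$sire) & is.na(idx$dam))
  if (any(is.na(idx$sire) != is.na(idx$dam)))
    stop("every non-founder must have both parents in the pedigree")
  if (2L * length(fndRow) != nrow(founders$haplotypes))
    stop("founder haplotype count does not match pedigree founders")
  chromIds <- unique(map$chromosome)
  chromIndex <- lapply(chromIds, function(ch) which(map$chromosome == ch))
  chromCM <- lapply(chromIndex, function(i) map$cM[i])
  chromLen <- vapply(seq_along(chromIds),
                     function(i) max(chromCM[[i]]) - min(chromCM[[i]]),
                     numeric(1))
  set.seed(seed)
  lab1 <- matrix(0L, n, L, dimnames = list(idx$id, map$snp))
  lab2 <- matrix(0L, n, L, dimnames = list(idx$id, map$snp))
  for (f in seq_along(fndRow)) {
    lab1[fndRow[f], ] <- 2L * f - 1L
    lab2[fndRow[f], ] <- 2L * f
  }
  for (i in seq_len(n)) {
    s <- idx$sire[i]
    if (is.na(s)) next
    d <- idx$dam[i]
    lab1[i, ] <- .dropGamete(lab1[s, ], lab2[s, ], chromIndex, chromCM, chromLen)
    lab2[i, ] <- .dropGamete(lab1[d, ], lab2[d, ], chromIndex, chromCM, chromLen)
  }
  H <- founders$haplotypes
  loci <- seq_len(L)
  codes <- matrix(NA_real_, n, L, dimnames = list(idx$id, map$snp))
  for (i in seq_len(n)) {
    codes[i, ] <- (H[cbind(lab1[i, ], loci)] + H[cbind(lab2[i, ], loci)]) / 2
  }
  pedOrdered <- Pedigree(id = idx$id,
                         sire = pedigree@sire[idx$order],
                         dam = pedigree@dam[idx$order],
                         sex = pedigree@sex[idx$order],
                         line = pedigree@line[idx$order])
  geno <- new("GenotypeData",
              codes = codes,
              line = pedOrdered@line,
              chromosome = as.integer(map$chromosome),
              positionBp = as.integer(map$bp),
              positionCM = as.numeric(map$cM),
              codedAllele = rep("A", L),
              otherAllele = rep("B", L))
  truth <- new("TruthRecord", labels1 = lab1, labels2 = lab2,
               truePedigree = pedOrdered,
               trueInbreeding = rowMeans(lab1 == lab2))
  list(genotypes = geno, truth = truth)
}

#' Realized kinship of pairs from tracked IBD labels
#'
#' For each pair, the mean over loci of (number of IBD allele pairs) / 4:
#' a parent-offspring pair with non-inbred, unrelated parents scores
#' exactly 0.25; full sibs average 0.25 with Mendelian-sampling spread.
#'
#' @param truth a \linkS4class{TruthRecord}.
#' @param pairs two-column matrix (or data.frame) of individual ids.
#' @return numeric realized kinship per pair.
#' @export
realizedKinship <- function(truth, pairs) {
  pairs <- as.matrix(pairs)
  ids <- rownames(truth@labels1)
  i <- match(pairs[, 1], ids); j <- match(pairs[, 2], ids)
  if (anyNA(i) || anyNA(j)) stop("pair ids not found in the truth record")
  vapply(seq_along(i), function(k) {
    a <- truth@labels1[i[k], ]; b <- truth@labels2[i[k], ]
    c_ <- truth@labels1[j[k], ]; d <- truth@labels2[j[k], ]
    mean((a == c_) + (a == d) + (b == c_) + (b == d)) / 4
  }, numeric(1))
}

#' Inject missingness and recorded-pedigree errors
#'
#' Sets each genotype missing independently with probability
#' \code{missingRate}. With probability \code{pedigreeErrorRate}, an
#' offspring's recorded sire is replaced by a different male drawn from
#' individuals earlier in pedigree order (which keeps the written pedigree
#' acyclic); the true pedigree is untouched and lives in the
#' \linkS4class{TruthRecord}.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param pedigree the true \linkS4class{Pedigree}.
#' @param missingRate,pedigreeErrorRate probabilities.
#' @param seed integer seed.
#' @return list with modified \code{genotypes} and the written (possibly
#'   erroneous) \code{pedigree}.
#' @export
injectArtifacts <- function(genotypes, pedigree, missingRate = 0,
                            pedigreeErrorRate = 0, seed = 1) {
  stopifnot(missingRate >= 0, missingRate <= 1,
            pedigreeErrorRate >= 0, pedigreeErrorRate <= 1)
  set.seed(seed)
  codes <- genotypeCodes(genotypes)
  if (missingRate > 0) {
    mask <- runif(length(codes)) < missingRate
    codes[mask] <- NA_real_
    genotypes@codes <- codes
  }
  sire <- pedigree@sire
  if (pedigreeErrorRate > 0) {
    males <- pedigree@id[pedigree@sex %in% "M"]
    pos <- match(pedigree@id, pedigree@id)  # pedigree assumed parent-first
    for (i in which(!is.na(sire))) {
      if (runif(1) < pedigreeErrorRate) {
        cand <- setdiff(intersect(males, pedigree@id[seq_len(i - 1)]), sire[i])
        if (length(cand)) sire[i] <- cand[sample.int(length(cand), 1)]
      }
    }
  }
  written <- Pedigree(id = pedigree@id, sire = sire, dam = pedigree@dam,
                      sex = pedigree@sex, line = pedigree@line)
  list(genotypes = genotypes, pedigree = written)
}

#' Simulate a complete pedigreed SNP dataset
#'
#' Convenience wrapper: \code{\link{buildPedigree}} ->
#' \code{\link{simulateFounders}} -> \code{\link{geneDrop}} ->
#' \code{\link{injectArtifacts}}. Fully reproducible from
#' \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{genotypes}, the written \code{pedigree}, the
#'   \code{truth} record and the founder \code{freq} vector (true
#'   coded-allele frequencies).
#' @export
simulateDataset <- function(config) {
  ped <- buildPedigree(config)
  fnd <- simulateFounders(config)
  gd <- geneDrop(ped, fnd, seed = .subSeed(config@seed, 3))
  art <- injectArtifacts(gd$genotypes, gd$truth@truePedigree,
                         missingRate = config@missingRate,
                         pedigreeErrorRate = config@pedigreeErrorRate,
                         seed = .subSeed(config@seed, 4))
  list(genotypes = art$genotypes, pedigree = art$pedigree,
       truth = gd$truth, freq = setNames(fnd$freq, fnd$map$snp))
}
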