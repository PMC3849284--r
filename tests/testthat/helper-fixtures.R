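# fixture builders shared across the suite; everything is generated in code

# GenotypeData straight from a code matrix (one chromosome by default)
makeGeno <- function(codes, chromosome = NULL, bp = NULL, line = "L1",
                     cM = NULL) {
  m <- ncol(codes)
  if (is.null(rownames(codes))) rownames(codes) <- sprintf("i%03d", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- sprintf("s%04d", seq_len(m))
  if (is.null(chromosome)) chromosome <- rep(1L, m)
  if (is.null(bp)) bp <- as.integer(stats::ave(seq_len(m), chromosome, FUN = seq_along) * 1000L)
  if (is.null(cM)) cM <- bp / 1e6
  new("GenotypeData", codes = codes, line = rep_len(line, nrow(codes)),
      chromosome = as.integer(chromosome), positionBp = as.integer(bp),
      positionCM = as.numeric(cM),
      codedAllele = rep("A", m), otherAllele = rep("B", m))
}

# n individuals under Hardy-Weinberg equilibrium at given frequencies
hweGeno <- function(n, p, seed = 1, line = "L1") {
  set.seed(seed)
  m <- length(p)
  codes <- matrix(rbinom(n * m, 2L, rep(p, each = n)) / 2, n, m)
  makeGeno(codes, line = line)
}

# random acyclic pedigree for property tests: each new individual draws
# parents among earlier individuals (or unknown)
randomPedigree <- function(n = 20, seed = 1, pUnknown = 0.3) {
  set.seed(seed)
  id <- sprintf("p%02d", seq_len(n))
  sex <- sample(rep_len(c("M", "F"), n))
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    males <- id[seq_len(i - 1)][sex[seq_len(i - 1)] == "M"]
    females <- id[seq_len(i - 1)][sex[seq_len(i - 1)] == "F"]
    if (length(males) && runif(1) > pUnknown) sire[i] <- sample(males, 1)
    if (length(females) && runif(1) > pUnknown) dam[i] <- sample(females, 1)
    # unknown-parent convention: either both known or both unknown keeps
    # gene dropping simple, but kinship code accepts single-known too
  }
  Pedigree(id = id, sire = sire, dam = dam, sex = sex)
}

# naive double-loop genomic kinship, the brute-force oracle
bruteKinship <- function(codes, p) {
  n <- nrow(codes)
  G <- matrix(NA_real_, n, n, dimnames = list(rownames(codes), rownames(codes)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; cnt <- 0
    for (k in seq_len(ncol(codes))) {
      xi <- codes[i, k]; xj <- codes[j, k]
      if (is.na(xi) || is.na(xj)) next
      num <- num + (xi - p[k]) * (xj - p[k]) / (p[k] * (1 - p[k]))
      cnt <- cnt + 1
    }
    G[i, j] <- num / cnt
  }
  G
}

# swap the coded allele of selected SNPs: x -> 1 - x, p -> 1 - p
flipCodes <- function(geno, snps) {
  codes <- genotypeCodes(geno)
  codes[, snps] <- 1 - codes[, snps]
  tmp <- geno@codedAllele[snps]
  geno@codedAllele[snps] <- geno@otherAllele[snps]
  geno@otherAllele[snps] <- tmp
  geno@codes <- codes
  geno
}

# trio population: nTrios independent (sire, dam, offspring) families,
# loci unlinked (one SNP per zero-length chromosome)
trioConfig <- function(nTrios, nLoci, seed = 1, mafRange = c(0.1, 0.5)) {
  simConfig(nFounders = 2 * nTrios, nGenerations = 1, offspringPerMating = 1,
            nChromosomes = nLoci, snpsPerChromosome = 1,
            chromosomeLengthCM = 0, mafRange = mafRange, seed = seed)
}
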