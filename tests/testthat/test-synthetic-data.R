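test_that("buildPedigree produces the declared family structure", {
  # smallest pedigree: 2 founders, one litter of 2 -> 4 records
  cfg <- simConfig(nFounders = 2, nGenerations = 1, offspringPerMating = 2,
                   nChromosomes = 1, snpsPerChromosome = 2)
  ped <- buildPedigree(cfg)
  expect_length(ped@id, 4)
  expect_equal(sum(is.na(ped@sire) & is.na(ped@dam)), 2)
  off <- which(!is.na(ped@sire))
  expect_true(all(ped@sire[off] %in% ped@id[1:2]))

  # one sire x 3 dams x 2 offspring: 6 offspring, 3 full-sib and 12
  # half-sib pairs by the shared-parent rule
  cfg <- simConfig(nFounders = 6, nGenerations = 1, offspringPerMating = 2,
                   matingScheme = "half_sib_heavy",
                   nChromosomes = 1, snpsPerChromosome = 2)
  ped <- buildPedigree(cfg)
  expect_length(ped@id, 12)
  expect_equal(length(unique(ped@sire[!is.na(ped@sire)])), 1)
  cls <- extractPairClasses(ped)
  expect_equal(nrow(cls$fullSibs), 3)
  expect_equal(nrow(cls$halfSibs), 12)
  expect_equal(nrow(cls$fatherOffspring), 6)
})

test_that("pedigrees are acyclic and generation-layered for varied configs", {
  for (scheme in c("random", "half_sib_heavy")) {
    cfg <- simConfig(nFounders = 8, nGenerations = 3, offspringPerMating = 3,
                     matingScheme = scheme, nChromosomes = 1,
                     snpsPerChromosome = 2, seed = 7)
    ped <- buildPedigree(cfg)
    ord <- topoOrder(ped)   # errors on a cycle
    pos <- match(seq_along(ped@id), ord)
    si <- match(ped@sire, ped@id)
    expect_true(all(pos[si[!is.na(si)]] < pos[!is.na(si)]))
    gen <- as.integer(sub("G(\\d+)_.*", "\\1", ped@id))
    off <- !is.na(ped@sire)
    expect_true(all(gen[match(ped@sire[off], ped@id)] == gen[off] - 1))
  }
  expect_error(simConfig(nFounders = 1), "founder")
})

test_that("founder LD blocks are perfect copies; LE founders are independent", {
  cfg <- simConfig(nFounders = 100, nGenerations = 1, offspringPerMating = 1,
                   nChromosomes = 2, snpsPerChromosome = 20, ldBlockSnps = 5,
                   seed = 3)
  fnd <- simulateFounders(cfg)
  codes <- (fnd$haplotypes[seq(1, 199, 2), ] + fnd$haplotypes[seq(2, 200, 2), ]) / 2
  for (b in seq(1, 16, by = 5)) {
    expect_equal(snpR2(codes[, b], codes[, b + 4]), 1)
    expect_identical(fnd$haplotypes[, b], fnd$haplotypes[, b + 4])
  }
  # across block boundary: independent loci, sample r^2 small
  expect_lt(snpR2(codes[, 5], codes[, 6]), 0.2)

  cfg <- simConfig(nFounders = 200, nGenerations = 1, offspringPerMating = 1,
                   nChromosomes = 1, snpsPerChromosome = 40, ldBlockSnps = 1,
                   seed = 4)
  fnd <- simulateFounders(cfg)
  codes <- (fnd$haplotypes[seq(1, 399, 2), ] + fnd$haplotypes[seq(2, 400, 2), ]) / 2
  adj <- vapply(1:39, function(k) snpR2(codes[, k], codes[, k + 1]), numeric(1))
  expect_lt(mean(adj), 0.05)
})

test_that("founder frequencies follow the configured MAF distribution", {
  cfg <- simConfig(nFounders = 400, nGenerations = 1, offspringPerMating = 1,
                   nChromosomes = 1, snpsPerChromosome = 30,
                   mafRange = c(0.3, 0.3), seed = 5)
  fnd <- simulateFounders(cfg)
  expect_true(all(fnd$freq == 0.3))
  realized <- colMeans(fnd$haplotypes)
  se <- sqrt(0.3 * 0.7 / 800)
  expect_true(all(abs(realized - 0.3) < 5 * se))
  # map sanity: strictly increasing bp within chromosome, cM present
  expect_true(all(diff(fnd$map$bp) > 0))
  expect_false(anyNA(fnd$map$cM))
})

test_that("gene dropping reproduces Mendelian IBD expectations", {
  # father-offspring: exactly one shared allele per locus -> 0.25 exactly
  cfg <- trioConfig(nTrios = 30, nLoci = 60, seed = 6)
  sim <- simulateDataset(cfg)
  cls <- extractPairClasses(sim$pedigree)
  rk <- realizedKinship(sim$truth, cls$fatherOffspring)
  expect_equal(rk, rep(0.25, length(rk)))

  # full sibs: mean 0.25 with Mendelian-sampling spread around it
  cfg <- simConfig(nFounders = 400, nGenerations = 1, offspringPerMating = 2,
                   nChromosomes = 200, snpsPerChromosome = 1,
                   chromosomeLengthCM = 0, seed = 8)
  sim <- simulateDataset(cfg)
  cls <- extractPairClasses(sim$pedigree)
  rk <- realizedKinship(sim$truth, cls$fullSibs)
  expect_equal(mean(rk), 0.25, tolerance = 0.02)
  expect_gt(sd(rk), 0.01)

  # averaging property: spread shrinks as the number of independent loci grows
  cfg2 <- simConfig(nFounders = 400, nGenerations = 1, offspringPerMating = 2,
                    nChromosomes = 1000, snpsPerChromosome = 1,
                    chromosomeLengthCM = 0, seed = 8)
  sim2 <- simulateDataset(cfg2)
  rk2 <- realizedKinship(sim2$truth, extractPairClasses(sim2$pedigree)$fullSibs)
  expect_lt(sd(rk2), sd(rk))
})

test_that("zero-length chromosomes transmit intact parental haplotypes", {
  cfg <- simConfig(nFounders = 4, nGenerations = 1, offspringPerMating = 2,
                   nChromosomes = 1, snpsPerChromosome = 50,
                   chromosomeLengthCM = 0, seed = 9)
  ped <- buildPedigree(cfg)
  fnd <- simulateFounders(cfg)
  gd <- geneDrop(ped, fnd, seed = 10)
  off <- which(!is.na(gd$truth@truePedigree@sire))
  for (i in off) {
    expect_length(unique(gd$truth@labels1[i, ]), 1)  # one paternal gamete
    expect_length(unique(gd$truth@labels2[i, ]), 1)
  }
})

test_that("artifact injection matches its configured rates", {
  cfg <- simConfig(nFounders = 20, nGenerations = 2, offspringPerMating = 4,
                   nChromosomes = 2, snpsPerChromosome = 50, seed = 11)
  base <- simulateDataset(cfg)
  # missing_rate = 0 leaves genotypes untouched
  art0 <- injectArtifacts(base$genotypes, base$truth@truePedigree,
                          missingRate = 0, seed = 1)
  expect_identical(genotypeCodes(art0$genotypes), genotypeCodes(base$genotypes))

  # missing_rate = 0.05: binomial count around n * rate
  art <- injectArtifacts(base$genotypes, base$truth@truePedigree,
                         missingRate = 0.05, seed = 2)
  nGeno <- length(genotypeCodes(base$genotypes))
  nMiss <- sum(is.na(genotypeCodes(art$genotypes)))
  expect_lt(abs(nMiss - 0.05 * nGeno), 5 * sqrt(nGeno * 0.05 * 0.95))

  # pedigree_error_rate = 1: every recorded sire differs from the truth
  art1 <- injectArtifacts(base$genotypes, base$truth@truePedigree,
                          pedigreeErrorRate = 1, seed = 3)
  truthSire <- base$truth@truePedigree@sire
  off <- !is.na(truthSire)
  expect_true(all(art1$pedigree@sire[off] != truthSire[off]))
})

test_that("the whole simulation is reproducible from its master seed", {
  cfg <- simConfig(nFounders = 10, nGenerations = 2, offspringPerMating = 3,
                   nChromosomes = 3, snpsPerChromosome = 30,
                   missingRate = 0.02, pedigreeErrorRate = 0.1, seed = 123)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(genotypeCodes(a$genotypes), genotypeCodes(b$genotypes))
  expect_identical(a$truth@labels1, b$truth@labels1)
  expect_identical(pedigreeTable(a$pedigree), pedigreeTable(b$pedigree))
})
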