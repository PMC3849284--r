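test_that("opposing-homozygote counts follow the Mendelian rules", {
  # true trio, no genotyping error: zero inconsistencies everywhere
  cfg <- trioConfig(nTrios = 10, nLoci = 120, seed = 31)
  sim <- simulateDataset(cfg)
  mc <- mendelianErrorCounts(sim$genotypes, sim$pedigree)
  expect_true(all(mc == 0))
  expect_gt(attr(mc, "nDuos"), 0)

  # a single forced opposing homozygote contributes exactly one count
  codes <- rbind(p1 = c(0, 1, 0.5), o1 = c(1, 1, 0))
  g <- makeGeno(codes)
  ped <- Pedigree(id = c("p1", "o1"), sire = c(NA, "p1"), dam = NA,
                  sex = c("M", "M"))
  expect_equal(as.vector(mendelianErrorCounts(g, ped)), c(1L, 0L, 0L))

  # missing genotypes skip the duo at that SNP
  codes["o1", 1] <- NA
  expect_equal(as.vector(mendelianErrorCounts(makeGeno(codes), ped)), c(0L, 0L, 0L))

  # unrelated individuals recorded as parent-offspring at p = 0.5:
  # expected error rate 2 p^2 (1-p)^2 = 0.125 per duo per SNP
  g2 <- hweGeno(100, rep(0.5, 400), seed = 32)
  ped2 <- Pedigree(id = sampleIds(g2),
                   sire = c(NA, sampleIds(g2)[seq_len(50)], rep(NA, 49)),
                   dam = NA, sex = "M")
  mc2 <- mendelianErrorCounts(g2, ped2)
  rate <- mean(mc2) / attr(mc2, "nDuos")
  expect_equal(rate, 0.125, tolerance = 0.05)
})

test_that("QC filters apply the printed boundary semantics", {
  # 10-sample line: one heterozygote, nine coded-0 homozygotes
  # -> MAF exactly 1/20 = 0.05, retained (rule is strictly less-than)
  codes <- cbind(snpA = c(0.5, rep(0, 9)),        # MAF 0.05: keep
                 snpB = c(0.5, 0.5, rep(0, 8)),   # MAF 0.10: keep
                 snpC = rep(c(0, 1), 5),          # MAF 0.50: keep
                 snpD = c(0.5, rep(NA, 9)),       # call rate 0.1: drop
                 snpE = c(rep(0.5, 4), rep(0, 6)))# MAF 0.2 but chromosome 19
  g <- makeGeno(codes, chromosome = c(1, 1, 1, 1, 19),
                bp = c(100, 200, 300, 400, 100))
  qc <- applyQC(g, pedigree = NULL, autosomes = 1:18)
  expect_identical(qc$report@removedMaf, character(0))
  expect_identical(qc$report@removedCallrate, "snpD")
  expect_identical(qc$report@removedSexchrom, "snpE")
  expect_identical(snpIds(qc$genotypes), c("snpA", "snpB", "snpC"))

  # pushing the threshold just above 0.05 removes the boundary SNP
  qc2 <- applyQC(g, mafMin = 0.051, autosomes = 1:18)
  expect_true("snpA" %in% qc2$report@removedMaf)
})

test_that("per-line MAF: a SNP failing in ANY line is removed", {
  codes <- cbind(s1 = c(rep(c(0, 1), 5), rep(0, 10)),  # L1 p=0.5, L2 fixed
                 s2 = rep(c(0, 1), 10))                # polymorphic in both
  g <- makeGeno(codes, line = rep(c("L1", "L2"), each = 10))
  qc <- applyQC(g)
  expect_identical(qc$report@removedMaf, "s1")
  expect_identical(snpIds(qc$genotypes), "s2")
})

test_that("individual missingness filter uses strictly-greater-than", {
  codes <- matrix(0.5, 4, 20, dimnames = list(sprintf("i%d", 1:4), NULL))
  codes[2, 1] <- NA                     # 5% missing exactly: retained
  codes[3, 1:3] <- NA                   # 15% missing: removed
  g <- makeGeno(codes)
  qc <- applyQC(g, callrateMin = 0.5, mafMin = 0)
  expect_identical(qc$report@removedIndividuals, "i3")
  expect_true("i2" %in% sampleIds(qc$genotypes))
})

test_that("QC is idempotent and attributes each SNP to one filter", {
  cfg <- simConfig(nFounders = 20, nGenerations = 2, offspringPerMating = 3,
                   nChromosomes = 4, snpsPerChromosome = 40,
                   mafRange = c(0.05, 0.5), missingRate = 0.03, seed = 33)
  sim <- simulateDataset(cfg)
  qc1 <- applyQC(sim$genotypes, sim$pedigree)
  r <- qc1$report
  removed <- c(r@removedMendel, r@removedMaf, r@removedCallrate, r@removedSexchrom)
  expect_equal(anyDuplicated(removed), 0)
  expect_equal(length(removed) + r@survivingSnps, ncol(sim$genotypes))
  qc2 <- applyQC(qc1$genotypes, sim$pedigree)
  expect_identical(snpIds(qc2$genotypes), snpIds(qc1$genotypes))
  expect_identical(sampleIds(qc2$genotypes), sampleIds(qc1$genotypes))
  # dropping a filter never shrinks the surviving set
  noMendel <- applyQC(sim$genotypes, pedigree = NULL)
  expect_gte(noMendel$report@survivingSnps, r@survivingSnps)
})

test_that("MAF decisions are invariant to which allele is coded", {
  g <- hweGeno(40, runif(30, 0.02, 0.5), seed = 34)
  flip <- seq(1, 30, by = 3)
  gf <- flipCodes(g, flip)
  expect_identical(applyQC(g)$report@removedMaf, applyQC(gf)$report@removedMaf)
})
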