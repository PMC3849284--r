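test_that("pair classes follow the shared-parent combinatorics", {
  # 1 sire x 3 dams x 2 offspring: 6 father-offspring, 3 full-sib pairs,
  # C(6,2) - 3 = 12 half-sib pairs
  ped <- Pedigree(id = c("s", "d1", "d2", "d3", sprintf("o%d", 1:6)),
                  sire = c(rep(NA, 4), rep("s", 6)),
                  dam = c(rep(NA, 4), rep(c("d1", "d2", "d3"), each = 2)),
                  sex = c("M", "F", "F", "F", rep_len(c("M", "F"), 6)))
  cls <- extractPairClasses(ped)
  expect_equal(nrow(cls$fatherOffspring), 6)
  expect_equal(nrow(cls$fullSibs), 3)
  expect_equal(nrow(cls$halfSibs), 12)
  # classes are disjoint
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  allKeys <- c(key(cls$fatherOffspring), key(cls$fullSibs), key(cls$halfSibs))
  expect_equal(anyDuplicated(allKeys), 0)

  # two unrelated families share no half sibs
  ped2 <- Pedigree(id = c("s1", "d1", "s2", "d2", "x1", "x2", "y1"),
                   sire = c(NA, NA, NA, NA, "s1", "s1", "s2"),
                   dam = c(NA, NA, NA, NA, "d1", "d1", "d2"),
                   sex = c("M", "F", "M", "F", "M", "M", "F"))
  cls2 <- extractPairClasses(ped2)
  expect_equal(nrow(cls2$halfSibs), 0)
  expect_equal(nrow(cls2$fullSibs), 1)
})

test_that("rejected paternity removes a pair from the father-offspring class", {
  ped <- Pedigree(id = c("s", "d", "a", "b"), sire = c(NA, NA, "s", "s"),
                  dam = c(NA, NA, "d", "d"), sex = c("M", "F", "M", "F"))
  pat <- data.frame(sire = c("s", "s"), offspring = c("a", "b"),
                    verdict = c("confirmed", "rejected"))
  cls <- extractPairClasses(ped, paternity = pat)
  expect_equal(nrow(cls$fatherOffspring), 1)
  expect_equal(cls$fatherOffspring[1, 2], "a")
})

test_that("the all-pairs population class counts C(n, 2) pairs", {
  ids <- sprintf("id%04d", seq_len(945))
  ped <- Pedigree(id = ids, sire = NA, dam = NA, sex = "M")
  K <- matrix(0.1, 945, 945, dimnames = list(ids, ids))
  res <- summarizeAndCorrelate(list(g = K), extractPairClasses(ped)[2],
                               samples = ids)
  n <- res$summary$n[res$summary$class == "allPairs"]
  expect_equal(n, choose(945, 2))
  expect_equal(n, 446040)
})

test_that("pedigree kinship is flat within class while genomic kinship
           spreads by Mendelian sampling", {
  # single bred generation from unrelated founders: every full-sib pair has
  # pedigree kinship exactly 0.25; the genomic estimates scatter around it
  cfg <- simConfig(nFounders = 60, nGenerations = 1, offspringPerMating = 4,
                   nChromosomes = 5, snpsPerChromosome = 80, seed = 91)
  sim <- simulateDataset(cfg)
  cls <- extractPairClasses(sim$pedigree)
  A <- aMatrix(sim$pedigree)
  K <- genomicKinship(sim$genotypes, freq = sim$freq)
  res <- summarizeAndCorrelate(list(pedigree = A / 2, genomic = K), cls)
  s <- res$summary
  pedFS <- s[s$class == "fullSibs" & s$estimator == "pedigree", ]
  genFS <- s[s$class == "fullSibs" & s$estimator == "genomic", ]
  expect_equal(pedFS$sd, 0, tolerance = 1e-12)
  expect_gt(genFS$sd, 0.01)
  expect_equal(pedFS$mean, 0.25)
  expect_equal(genFS$mean, 0.25, tolerance = 0.1)
  s0 <- s[s$n > 0, ]   # a class with no pairs (half sibs here) stays NA
  expect_true(all(s0$min <= s0$mean & s0$mean <= s0$max))
  # father-offspring genomic estimates vary less than full-sib ones
  genFO <- s[s$class == "fatherOffspring" & s$estimator == "genomic", ]
  expect_lt(genFO$sd, genFS$sd)
})

test_that("summaries and correlations reproduce the study's comparison surface", {
  # deeper pedigree from a narrow founder base, so pedigree kinship varies
  # within classes and within-class correlations are defined
  cfg <- simConfig(nFounders = 12, nGenerations = 3, offspringPerMating = 3,
                   nChromosomes = 5, snpsPerChromosome = 80, seed = 92)
  sim <- simulateDataset(cfg)
  qc <- applyQC(sim$genotypes, sim$pedigree)
  pat <- checkPaternity(qc$genotypes, pedigree = sim$pedigree)
  cls <- extractPairClasses(sim$pedigree, samples = sampleIds(qc$genotypes),
                            paternity = pat)
  A <- aMatrix(sim$pedigree)
  K <- genomicKinship(qc$genotypes, freq = sim$freq)
  res <- summarizeAndCorrelate(list(pedigree = A / 2, genomic = K), cls,
                               samples = sampleIds(qc$genotypes))

  # an estimator correlated with itself gives r = 1
  self <- summarizeAndCorrelate(list(a = K, b = K), cls["fullSibs"])
  expect_equal(self$correlations$r, 1, tolerance = 1e-12)

  # population-wide agreement beats within-class agreement: between-class
  # spread dominates both estimators
  rAll <- res$correlations$r[res$correlations$class == "allPairs"]
  rFS <- res$correlations$r[res$correlations$class == "fullSibs"]
  expect_gt(rAll, rFS)

  # fewer than 3 pairs: correlation withheld
  tiny <- summarizeAndCorrelate(list(pedigree = A / 2, genomic = K),
                                list(two = cls$fullSibs[1:2, , drop = FALSE]))
  expect_true(is.na(tiny$correlations$r))
})

test_that("inbreeding tables summarize and correlate per line", {
  fped <- setNames(c(0, 0.1, 0.2, 0.05), sprintf("i%d", 1:4))
  fgen <- setNames(c(-0.02, 0.12, 0.18, 0.07), sprintf("i%d", 1:4))
  tb <- inbreedingTable(list(pedigree = fped, genomic = fgen))
  expect_equal(nrow(tb$summary), 2)
  expect_equal(tb$summary$mean[1], mean(fped))
  expect_equal(tb$correlations$r, cor(fped, fgen))
})
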