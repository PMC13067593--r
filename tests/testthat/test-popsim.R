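test_that("burn-in without mutation from a monomorphic start is an empty panel", {
  expect_error(wfBurnIn(2, genomeMap(1, 50), 100, 0, 20, seed = 1),
               "empty panel")
})

test_that("burn-in is reproducible for identical seeds", {
  a <- wfBurnIn(20, genomeMap(2, 80), 400, 2e-4, 100, seed = 7)
  b <- wfBurnIn(20, genomeMap(2, 80), 400, 2e-4, 100, seed = 7)
  expect_identical(haplotypes(a), haplotypes(b))
  expect_identical(alleleFreqs(a), alleleFreqs(b))
})

test_that("burn-in diversity approaches the neutral equilibrium expectation", {
  ne <- 100; mu <- 1e-4
  p <- wfBurnIn(ne, genomeMap(1, 100), 2000, mu, 10 * ne, seed = 13)
  q <- alleleFreqs(p)
  H <- sum(2 * q * (1 - q) * (2 * ne) / (2 * ne - 1)) / p@nSitesSimulated
  theta <- 4 * ne * mu
  expect_equal(H, theta / (1 + theta), tolerance = 0.25)
})

test_that("locus panels are disjoint, sized, and respect the MAF filter", {
  # deterministic panel: 10 sites at frequency 0.3, one rare site at 0.005
  H <- 200
  freq <- c(rep(0.3, 10), 0.005)
  haps <- sapply(freq, function(f) as.integer(seq_len(H) <= round(f * H)))
  panel <- new("HaplotypePanel", haplotypes = t(haps),
               map = geneticMap(rep(1L, 11), seq(5, 55, 5), 100),
               freq = freq, nSitesSimulated = 11L)
  pp <- sampleLociPanels(panel, 3, 3, 3, mafMin = 0.01, seed = 1)
  expect_length(pp@snpIdx, 3)
  expect_length(pp@neutralIdx, 3)
  expect_length(pp@qtlIdx, 3)
  all3 <- c(pp@snpIdx, pp@neutralIdx, pp@qtlIdx)
  expect_false(anyDuplicated(all3) > 0)
  # brute-force filter: the MAF-0.005 site (index 11) is eligible nowhere
  eligible <- which(pmin(freq, 1 - freq) > 0.01)
  expect_true(all(all3 %in% eligible))
  expect_false(11L %in% all3)
  expect_error(sampleLociPanels(panel, 8, 2, 2, mafMin = 0.01),
               "shortfall")
})

test_that("trait scaling fixes var(TBV) = 1 and the residual variance", {
  set.seed(2)
  d <- matrix(rbinom(50 * 200, 2, 0.4), 50, 200)
  tr <- buildTrait(d, h2 = 0.25, seed = 3)
  expect_equal(var(computeTbvOracle(d, tr@qtlEffects)), 1, tolerance = 1e-8)
  expect_equal(tr@sigmaE2, 3)
  # single QTL, raw effect 5, dosage sd 0.4 -> scaled effect 1 / 0.4 = 2.5
  d1 <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2), 1)
  d1 <- d1[, c(1:4, 5:8, 9, 10), drop = FALSE]
  sdDos <- sd(d1[1, ])
  tr1 <- buildTrait(d1, h2 = 0.5, effects = 5)
  expect_equal(tr1@qtlEffects, 1 / sdDos)
  expect_error(buildTrait(matrix(1, 1, 5), 0.25, effects = 2),
               "scaling error")
})

test_that("meiosis respects trivial limits and the Poisson crossover model", {
  # near-zero map length: gamete equals one parental haplotype
  map0 <- geneticMap(rep(1L, 10), seq_len(10) * 1e-10, 1e-8)
  al <- cbind(rep(0L, 10), rep(1L, 10))
  pop <- manualFounders(al, map0)
  hits <- replicate(40, {
    g <- simulateMeiosis(pop, 1)
    all(g$alleles == 0L) || all(g$alleles == 1L)
  })
  expect_true(all(hits))
  picks <- replicate(200, {
    g <- simulateMeiosis(pop, 1)
    all(g$alleles == 0L)
  })
  expect_gt(mean(picks), 0.35)  # fair coin per chromosome
  expect_lt(mean(picks), 0.65)
  # identical haplotypes recombine to themselves
  mapL <- geneticMap(rep(1L, 50), seq(1, 99, 2), 100)
  pop2 <- manualFounders(cbind(rep(1L, 50), rep(1L, 50)), mapL)
  g <- simulateMeiosis(pop2, 1, seed = 4)
  expect_identical(g$alleles, rep(1L, 50))
  # crossover count on a 1-Morgan chromosome averages 1 (label switches)
  map1 <- geneticMap(rep(1L, 400), seq(0.125, 99.9, 0.25), 100)
  popX <- manualFounders(cbind(rep(0L, 400), rep(1L, 400)), map1)
  set.seed(5)
  gam <- ocsim:::cpp_make_gametes(popX@alleles, popX@labels,
                                  rep(1L, 20000), map1@chrom, map1@posCm,
                                  map1@chromLengths)
  switches <- colSums(gam$alleles[-1, ] != gam$alleles[-400, ])
  expect_equal(mean(switches), 1, tolerance = 0.035)
})

test_that("allele and founder-label tracks share identical breakpoints", {
  sim <- smallSim(seed = 21, nGenerations = 3)
  pop <- sim$pop
  founders <- pop@ped$id[pop@ped$generation == 0]
  fh <- haplotypes(pop, individuals = founders)
  # an allele's founder label must point at a founder haplotype carrying
  # that allele at that locus (full gene-drop replay)
  S <- nLoci(pop)
  labs <- pop@labels
  expect_true(all(pop@alleles == fh[cbind(rep(seq_len(S), ncol(labs)),
                                          as.vector(labs))]))
})

test_that("random mating phase founds, labels and reproduces correctly", {
  sim <- smallSim(seed = 31, nGenerations = 0)
  expect_equal(nIndiv(sim$pop), 30)
  expect_identical(sort(unique(as.vector(sim$pop@labels))), 1:60)
  expect_error(randomMatingPhase(sim$panel, sim$panels, 0, 5, 10, 1,
                                 sim$trait), "configuration error")
  expect_error(randomMatingPhase(sim$panel, sim$panels, 5, 5, 1, 1,
                                 sim$trait), "configuration error")
  # stored TBVs equal TBVs recomputed from genotypes at every generation
  sim2 <- smallSim(seed = 32, nGenerations = 3)
  d <- dosages(sim2$pop, loci = sim2$pop@panels@qtlIdx)
  expect_equal(tbv(sim2$pop),
               as.vector(crossprod(d, sim2$trait@qtlEffects)))
})

test_that("inbreeding under random mating follows the pool-size recurrence", {
  nGen <- 5
  f <- sapply(1:5, function(r) {
    sim <- smallSim(seed = 40 + r, nMales = 15, nFemales = 15,
                    nOffspring = 60, nGenerations = nGen)
    ids <- pedigree(sim$pop)$id[pedigree(sim$pop)$generation == nGen]
    mean(ibdInbreeding(sim$pop, individuals = ids))
  })
  expected <- expectedFRecurrence(15, 15, nGen)
  expect_equal(mean(f), expected, tolerance = 0.25)
  # and stays compatible with the lag-free approximation 1 - (1 - dF)^t
  expect_equal(mean(f), 1 - (1 - 1 / 60)^nGen, tolerance = 0.45)
})

test_that("neutral-locus frequencies are a martingale under random mating", {
  dq <- sapply(1:6, function(r) {
    sim <- smallSim(seed = 50 + r, nGenerations = 3)
    pop <- sim$pop
    g0 <- pedigree(pop)$id[pedigree(pop)$generation == 0]
    g3 <- pedigree(pop)$id[pedigree(pop)$generation == 3]
    mean(alleleFreqs(pop, g3, loci = pop@panels@neutralIdx) -
           alleleFreqs(pop, g0, loci = pop@panels@neutralIdx))
  })
  expect_lt(abs(mean(dq)), 0.01)
})

test_that("phenotypes realize the trait model", {
  map1 <- geneticMap(1L, 50, 100)
  n <- 8000
  al <- matrix(0L, 1, 2 * n)
  pop <- manualFounders(al, map1, sexes = rep(c(1L, 2L), n / 2))
  pop@tbv <- rnorm(n)
  tr0 <- new("TraitArchitecture", qtlEffects = 1, h2 = 1, sigmaE2 = 0)
  p0 <- assignPhenotypes(pop, tr0, seed = 6)
  expect_equal(phenotypes(p0), tbv(p0))
  tr3 <- new("TraitArchitecture", qtlEffects = 1, h2 = 0.25, sigmaE2 = 3)
  p3 <- assignPhenotypes(pop, tr3, seed = 7)
  p3b <- assignPhenotypes(pop, tr3, seed = 7)
  expect_identical(phenotypes(p3), phenotypes(p3b))
  # h2: regression of TBV on phenotype has slope var(u)/var(y) = 0.25
  slope <- unname(coef(lm(tbv(p3) ~ phenotypes(p3)))[2])
  expect_equal(slope, 0.25, tolerance = 0.1)
})
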