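test_that("VanRaden matrix matches the closed formula", {
  # single locus at p = 0.5, two heterozygotes: centred dosages are zero
  d <- matrix(c(1, 1), 1)
  G <- gVanRaden(d, 0.5)
  expect_equal(unname(relValues(G)), matrix(0, 2, 2))
  # one homozygote carrier: diagonal (2 - 1)^2 / (2 * 0.25) = 2
  d2 <- matrix(c(2, 1), 1)
  expect_equal(relValues(gVanRaden(d2, 0.5))[1, 1], 2)
  # with current sample frequencies the centred dosages have zero column
  # means, so the matrix row sums average zero
  set.seed(4)
  d3 <- matrix(rbinom(50 * 20, 2, 0.35), 50, 20)
  p <- rowMeans(d3) / 2
  keep <- p > 0 & p < 1
  G3 <- relValues(gVanRaden(d3[keep, , drop = FALSE], p[keep]))
  expect_lt(abs(mean(rowSums(G3))), 1e-10)
  expect_error(gVanRaden(matrix(c(0, 0), 1), 0), "zero denominator")
})

test_that("true IBD matrix reproduces descent exactly", {
  S <- 40
  map <- mapOfRel(S)
  al <- matrix(0L, S, 4)  # two founders
  pop <- manualFounders(al, map)
  G <- relValues(gTrueIbd(pop, loci = seq_len(S)))
  expect_equal(unname(diag(G)), c(1, 1))          # founders are non-inbred
  expect_equal(G[1, 2], 0)                # and unrelated
  # parent-offspring with non-inbred unrelated parents is exactly 0.5:
  # the child's paternal gamete splits x : (1 - x) between the sire's two
  # haplotypes and the four-combination average collapses to 1/2
  set.seed(9)
  g1 <- simulateMeiosis(pop, 1)
  g2 <- simulateMeiosis(pop, 2)
  pop2 <- addChild(pop, 1, 2, g1$alleles, g1$labels, g2$alleles, g2$labels)
  G2 <- relValues(gTrueIbd(pop2, loci = seq_len(S)))
  expect_equal(G2[1, 3], 0.5)
  expect_equal(G2[2, 3], 0.5)
  expect_equal(G2[3, 3], 1)
  # non-inbred identical twins: offdiag (1 + 0 + 0 + 1) / 2 = 1
  twin <- addChild(pop2, 1, 2, g1$alleles, g1$labels, g2$alleles, g2$labels)
  G3 <- relValues(gTrueIbd(twin, loci = seq_len(S)))
  expect_equal(G3[3, 4], 1)
  # a completely inbred individual has diagonal 2 and clones of an inbred
  # line have relationship 2
  inbred <- addChild(pop, 1, 1, g1$alleles, g1$labels, g1$alleles, g1$labels)
  inbred <- addChild(inbred, 1, 1, g1$alleles, g1$labels, g1$alleles,
                     g1$labels)
  G4 <- relValues(gTrueIbd(inbred, loci = seq_len(S)))
  expect_equal(G4[3, 3], 2)
  expect_equal(G4[3, 4], 2)
})

test_that("IBD diagonal equals the naive per-locus loop", {
  sim <- smallSim(seed = 71, nGenerations = 3)
  pop <- sim$pop
  ids <- sample(pedigree(pop)$id, 20)
  got <- ibdInbreeding(pop, individuals = ids)
  labs <- founderLabels(pop, individuals = ids,
                        loci = pop@panels@snpIdx)
  naive <- sapply(seq_along(ids), function(a)
    mean(labs[, 2 * a - 1] == labs[, 2 * a]))
  expect_equal(unname(got), naive)
  G <- gTrueIbd(pop, individuals = ids)
  expect_equal(unname(inbreedingCoef(G)), naive)
})

test_that("relationship constructors are permutation-equivariant", {
  sim <- smallSim(seed = 72, nMales = 5, nFemales = 5, nOffspring = 24,
                  nGenerations = 2)
  pop <- sim$pop
  ids <- pedigree(pop)$id[pedigree(pop)$generation == 2]
  perm <- sample(ids)
  o <- match(perm, ids)
  Gi <- relValues(gTrueIbd(pop, individuals = ids))
  Gp <- relValues(gTrueIbd(pop, individuals = perm))
  expect_equal(Gp, Gi[o, o], ignore_attr = TRUE)
  d <- dosages(pop, individuals = ids, loci = pop@panels@snpIdx)
  p <- alleleFreqs(pop, ids, loci = pop@panels@snpIdx)
  Gv <- relValues(gVanRaden(d, p))
  Gvp <- relValues(gVanRaden(d[, o], p))
  expect_equal(Gvp, Gv[o, o], ignore_attr = TRUE)
})

test_that("ROH matrix implements the segment-length formulas", {
  # no segments: identity-like matrix
  empty <- new("SegmentSet",
               segments = data.frame(indivA = numeric(0), hapA = numeric(0),
                                     indivB = numeric(0), hapB = numeric(0),
                                     chrom = numeric(0), startCm = numeric(0),
                                     endCm = numeric(0), nSnps = numeric(0)),
               L = 100, ids = 1:3)
  G <- relValues(gRoh(empty))
  expect_equal(unname(G), diag(3))
  # one within-individual segment of length L/2 gives diagonal 1.5
  one <- new("SegmentSet",
             segments = data.frame(indivA = 1, hapA = 1, indivB = 1,
                                   hapB = 2, chrom = 1, startCm = 10,
                                   endCm = 60, nSnps = 30),
             L = 100, ids = 1:2)
  expect_equal(relValues(gRoh(one))[1, 1], 1.5)
  # clones of a fully inbred line: all four combinations full length
  clones <- new("SegmentSet",
                segments = data.frame(indivA = c(1, 2, 1, 1, 2, 2),
                                      hapA = c(1, 1, 1, 1, 2, 2),
                                      indivB = c(1, 2, 2, 2, 1, 1),
                                      hapB = c(2, 2, 1, 2, 1, 2),
                                      chrom = 1, startCm = 0, endCm = 100,
                                      nSnps = 50),
                L = 100, ids = 1:2)
  Gc <- relValues(gRoh(clones))
  expect_equal(Gc[1, 2], 2)
  expect_equal(unname(diag(Gc)), c(2, 2))
})

test_that("ROH relationships never increase with the length threshold", {
  sim <- smallSim(seed = 73, nMales = 5, nFemales = 5, nOffspring = 24,
                  nGenerations = 3)
  ids <- pedigree(sim$pop)$id[pedigree(sim$pop)$generation == 3]
  mats <- lapply(c(1, 5, 10), function(len)
    relValues(gRoh(collectPopulationSegments(sim$pop, individuals = ids,
                                             minSnps = 5, minLenCm = len),
                   minLenCm = len)))
  expect_true(all(mats[[2]] <= mats[[1]] + 1e-12))
  expect_true(all(mats[[3]] <= mats[[2]] + 1e-12))
})

test_that("segregation indicators are read off phased heterozygous parents", {
  S <- 30
  map <- mapOfRel(S)
  # founders fully heterozygous and phased: hap1 all 0, hap2 all 1
  al <- matrix(rep(c(0L, 1L), S * 2), S, 4, byrow = TRUE)
  pop <- manualFounders(al, map)
  set.seed(21)
  g1 <- simulateMeiosis(pop, 1)
  g2 <- simulateMeiosis(pop, 2)
  pop2 <- addChild(pop, 1, 2, g1$alleles, g1$labels, g2$alleles, g2$labels)
  ind <- inferSegregationIndicators(pop2, baseGeneration = 0,
                                    loci = seq_len(S))
  expect_true(all(ind@statusPat[, 3] == 0))
  # the allele received reveals the transmitting haplotype exactly
  expect_equal(ind@pat[, 3], g1$alleles + 1L)
  expect_equal(ind@mat[, 3], g2$alleles + 1L)
})

test_that("unknown indicators copy the nearest known locus or a fair coin", {
  map <- geneticMap(c(1L, 1L, 1L, 2L, 2L), c(5, 10, 40, 10, 20),
                    c(100, 100))
  # sire heterozygous only at locus 2 (10 cM); chromosome 2 uninformative
  sire <- c(0L, 0L, 0L, 0L, 0L)
  sire2 <- c(0L, 1L, 0L, 0L, 0L)
  dam <- c(0L, 0L, 0L, 0L, 0L)
  al <- cbind(sire, sire2, dam, dam)
  pop <- manualFounders(al, map)
  child_pat <- c(0L, 1L, 0L, 0L, 0L)   # received sire hap2 at the known locus
  child_mat <- dam
  pop2 <- addChild(pop, 1, 2, child_pat, rep(2L, 5), child_mat, rep(3L, 5))
  ind <- inferSegregationIndicators(pop2, baseGeneration = 0,
                                    loci = 1:5, seed = 31)
  # loci at 5 and 40 cM copy the known indicator at 10 cM
  expect_equal(unname(ind@pat[1:3, 3]), c(2L, 2L, 2L))
  expect_equal(unname(ind@statusPat[1:3, 3]), c(1L, 0L, 1L))
  # chromosome 2 has no known locus: one coin applied to both loci
  expect_equal(ind@pat[4, 3], ind@pat[5, 3])
  expect_true(all(ind@statusPat[4:5, 3] == 2L))
  # a homozygous-parent mismatch is a Mendelian inconsistency
  bad <- pop2
  bad@alleles[1, 5] <- 1L
  expect_error(inferSegregationIndicators(bad, baseGeneration = 0,
                                          loci = 1:5),
               "Mendelian")
})

test_that("FGLA equals true IBD when every indicator is known", {
  S <- 40
  map <- mapOfRel(S)
  nF <- 8
  al <- matrix(rep(c(0L, 1L), S * nF), S, 2 * nF, byrow = TRUE)
  pop <- manualFounders(al, map)
  trait0 <- new("TraitArchitecture", qtlEffects = numeric(0), h2 = 0.25,
                sigmaE2 = 3)
  set.seed(41)
  # children of fully heterozygous phased founders: every transmission is
  # determinable, so the gene-drop is fully informed
  pop <- ocsim:::makeOffspring(pop, c(1, 1, 3, 3, 5, 7), c(2, 2, 4, 4, 6, 8),
                               1, trait0)
  ind <- inferSegregationIndicators(pop, baseGeneration = 0,
                                    loci = seq_len(S))
  expect_true(all(ind@statusPat[, -(1:nF)] == 0))
  Gf <- relValues(gFgla(pop, ind, loci = seq_len(S)))
  Gt <- relValues(gTrueIbd(pop, loci = seq_len(S)))
  expect_equal(Gf, Gt, ignore_attr = TRUE)
  # base animals themselves have diagonal 1 and off-diagonal 0
  expect_equal(Gf[1:nF, 1:nF], diag(nF), ignore_attr = TRUE)
})

test_that("FGLA with uninformative genotypes averages to the pedigree A", {
  S <- 9
  map <- geneticMap(rep(1:3, each = 3), rep(c(10, 50, 90), 3),
                    rep(100, 3))
  nF <- 6
  al <- matrix(0L, S, 2 * nF)   # all-homozygous founders: nothing is known
  pop <- manualFounders(al, map)
  trait0 <- new("TraitArchitecture", qtlEffects = numeric(0), h2 = 0.25,
                sigmaE2 = 3)
  set.seed(42)
  pop <- ocsim:::makeOffspring(pop, c(1, 1, 3), c(2, 4, 6), 1, trait0)
  pop <- ocsim:::makeOffspring(pop, c(7, 7), c(8, 9), 2, trait0)
  acc <- matrix(0, nIndiv(pop), nIndiv(pop))
  nDraw <- 400
  set.seed(43)
  for (k in seq_len(nDraw)) {
    ind <- inferSegregationIndicators(pop, baseGeneration = 0,
                                      loci = seq_len(S))
    expect_true(all(ind@statusPat[, -(1:nF)] == 2))
    acc <- acc + relValues(gFgla(pop, ind, loci = seq_len(S)))
  }
  A <- pedigreeA(pedigree(pop))
  expect_lt(max(abs(acc / nDraw - A)), 0.09)
  expect_lt(mean(abs(acc / nDraw - A)), 0.02)
})

test_that("pedigree A follows the tabular rules", {
  ped <- data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3), dam = c(0, 0, 2, 2, 4))
  A <- pedigreeA(ped)
  expect_equal(A[3, 4], 0.5)        # full sibs
  expect_equal(A[5, 5], 1.25)       # parents are full sibs
  expect_equal(A[1, 3], 0.5)
  expect_equal(A[1, 2], 0)
})
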