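mapOf <- function(pos, chromLen = 100, chrom = rep(1L, length(pos)))
  geneticMap(chrom, pos, rep(chromLen, max(chrom)))

test_that("segment detection handles the canonical cases", {
  map <- mapOf(seq(0, 50, length.out = 30))
  h <- rep(1L, 30)
  s <- detectSharedSegments(h, h, map, minSnps = 20, minLenCm = 5)
  expect_equal(nrow(s), 1)
  expect_equal(s$startCm, 0)
  expect_equal(s$endCm, 50)
  expect_equal(s$nSnps, 30)
  # haplotypes differing at every SNP share nothing
  s2 <- detectSharedSegments(rep(0L, 30), rep(1L, 30), map, 20, 5)
  expect_equal(nrow(s2), 0)
  # a 25-SNP run spanning only 4 cM fails the length filter
  map4 <- mapOf(seq(0, 4, length.out = 25))
  s3 <- detectSharedSegments(rep(1L, 25), rep(1L, 25), map4, 20, 5)
  expect_equal(nrow(s3), 0)
  expect_error(detectSharedSegments(rep(1L, 10), rep(1L, 9), mapOf(1:10)),
               "equal length")
})

test_that("segment detection equals the naive run-scan oracle", {
  set.seed(11)
  for (r in 1:20) {
    S <- 120
    chrom <- sort(sample(1:2, S, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(S), chrom), function(i)
      sort(runif(length(i), 0, 100))))
    map <- geneticMap(chrom, pos, c(100, 100))
    a <- sample(0:1, S, replace = TRUE)
    b <- a
    flip <- sample(S, rbinom(1, S, 0.2))
    b[flip] <- 1L - b[flip]
    minSnps <- sample(2:8, 1)
    minLen <- runif(1, 0, 10)
    got <- detectSharedSegments(a, b, map, minSnps, minLen)
    want <- naiveSegments(a, b, map, minSnps, minLen)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                 tolerance = 1e-12)
    # symmetry
    rev <- detectSharedSegments(b, a, map, minSnps, minLen)
    expect_equal(got, rev)
  }
})

test_that("detection is monotone in both filters", {
  set.seed(12)
  S <- 200
  map <- mapOf(sort(runif(S, 0, 100)))
  a <- sample(0:1, S, replace = TRUE)
  b <- a; flip <- sample(S, 30); b[flip] <- 1L - b[flip]
  covered <- function(s) if (nrow(s)) sum(s$endCm - s$startCm) else 0
  base <- detectSharedSegments(a, b, map, 3, 1)
  expect_gte(covered(base), covered(detectSharedSegments(a, b, map, 6, 1)))
  expect_gte(covered(base), covered(detectSharedSegments(a, b, map, 3, 5)))
  expect_gte(nrow(base), nrow(detectSharedSegments(a, b, map, 6, 5)))
})

test_that("overlap merging unions half-open intervals", {
  s <- data.frame(chrom = 1, startCm = c(10, 20), endCm = c(30, 40),
                  nSnps = c(5, 5))
  m <- mergeOverlapping(s)
  expect_equal(nrow(m), 1)
  expect_equal(m$startCm, 10)
  expect_equal(m$endCm, 40)
  expect_equal(sum(m$endCm - m$startCm), 30)
  # book-ended [a,b) + [b,c) coalesce
  s2 <- data.frame(chrom = 1, startCm = c(10, 20), endCm = c(20, 25),
                   nSnps = c(2, 2))
  expect_equal(nrow(mergeOverlapping(s2)), 1)
  # disjoint intervals are untouched
  s3 <- data.frame(chrom = 1, startCm = c(10, 30), endCm = c(20, 40),
                   nSnps = c(2, 2))
  expect_equal(mergeOverlapping(s3)[, c("startCm", "endCm")],
               s3[, c("startCm", "endCm")])
})

test_that("merged length matches a point-sampling union estimate", {
  set.seed(13)
  for (r in 1:5) {
    k <- 30
    st <- runif(k, 0, 90)
    en <- st + runif(k, 0.5, 15)
    segs <- data.frame(chrom = 1, startCm = st, endCm = en, nSnps = 1)
    m <- mergeOverlapping(segs)
    expect_true(all(diff(m$startCm) > 0))
    expect_true(all(m$endCm[-nrow(m)] < m$startCm[-1]))
    grid <- seq(0, 105, by = 0.01)
    inAny <- rowSums(outer(grid, st, ">=") & outer(grid, en, "<")) > 0
    expect_equal(sum(m$endCm - m$startCm), sum(inAny) * 0.01,
                 tolerance = 0.02)
    expect_lte(sum(m$endCm - m$startCm), sum(en - st) + 1e-12)
  }
})

test_that("population collection equals naive pairwise detection", {
  sim <- smallSim(seed = 61, nMales = 5, nFemales = 5, nOffspring = 24,
                  nGenerations = 2)
  pop <- sim$pop
  ids <- pedigree(pop)$id[pedigree(pop)$generation == 2]
  segset <- collectPopulationSegments(pop, individuals = ids, minSnps = 10,
                                      minLenCm = 1)
  segs <- segments(segset)
  sub <- ocsim:::subsetMap(pop@map, pop@panels@snpIdx)
  H <- haplotypes(pop, individuals = ids, loci = pop@panels@snpIdx)
  total <- 0
  for (a in seq_along(ids)) {
    combos <- list(c(2 * a - 1, 2 * a, a, 1, a, 2))
    if (a < length(ids)) for (b in (a + 1):length(ids))
      combos <- c(combos, list(c(2 * a - 1, 2 * b - 1, a, 1, b, 1),
                               c(2 * a - 1, 2 * b, a, 1, b, 2),
                               c(2 * a, 2 * b - 1, a, 2, b, 1),
                               c(2 * a, 2 * b, a, 2, b, 2)))
    for (cb in combos) {
      want <- naiveSegments(H[, cb[1]], H[, cb[2]], sub, 10, 1)
      got <- segs[segs$indivA == cb[3] & segs$hapA == cb[4] &
                    segs$indivB == cb[5] & segs$hapB == cb[6], , drop = FALSE]
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(sort(got$startCm), sort(want$startCm))
        expect_equal(sum(got$endCm - got$startCm),
                     sum(want$endCm - want$startCm))
      }
      total <- total + nrow(want)
    }
  }
  expect_equal(nrow(segs), total)
})

test_that("clones are covered end to end and strangers not at all", {
  # identical fully homozygous clones: every haplotype pair shares one
  # genome-length segment per chromosome
  S <- 60
  map <- geneticMap(rep(1:2, each = 30),
                    rep(seq(0, 90, length.out = 30), 2), c(100, 100))
  al <- matrix(1L, S, 6)
  pop <- manualFounders(al, map)
  segset <- collectPopulationSegments(pop, minSnps = 10, minLenCm = 5,
                                      loci = seq_len(S))
  segs <- segments(segset)
  nPairs <- 3 + 4 * choose(3, 2)      # within pairs + cross combos
  expect_equal(nrow(segs), 2 * nPairs)  # one segment per chromosome
  expect_true(all(segs$nSnps == 30))
  # mosaic strangers with a large minimum length share nothing
  set.seed(3)
  al2 <- matrix(as.integer(runif(S * 6) < 0.5), S, 6)
  pop2 <- manualFounders(al2, map)
  expect_equal(nrow(segments(collectPopulationSegments(pop2, minSnps = 10,
                                                       minLenCm = 50,
                                                       loci = seq_len(S)))),
               0)
})

test_that("segments from a 5-generation-deep ancestor average 10 cM", {
  len <- dropSharedSegmentLengths(depth = 5, chromLenCm = 2000,
                                  minSegments = 4000,
                                  batchPairs = 30000L, seed = 17)
  expect_gte(length(len), 4000)
  expect_equal(mean(len), 100 / (2 * 5), tolerance = 0.1)
})

test_that("segment export round-trips through TSV", {
  sim <- smallSim(seed = 62, nMales = 4, nFemales = 4, nOffspring = 24,
                  nGenerations = 1)
  segset <- collectPopulationSegments(sim$pop, minSnps = 10, minLenCm = 1)
  f <- tempfile(fileext = ".tsv")
  writeSegmentsTsv(segset, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(segments(segset)))
  expect_equal(back$startCm, segments(segset)$startCm)
})
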