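# Shared fixtures, all generated in code.

# small historic panel + locus panels + trait + random-mating population
smallSim <- function(seed = 5, nMales = 15, nFemales = 15, nOffspring = 60,
                     nGenerations = 4, nSnp = 400, nNeutral = 120,
                     nQtl = 60, ne = 60, h2 = 0.25) {
  panel <- wfBurnIn(ne, genomeMap(3, 60), 5000, 2.5e-4, 600, seed = seed)
  panels <- sampleLociPanels(panel, nSnp, nNeutral, nQtl, 0.01,
                             seed = seed + 1)
  qd <- qtlDosagesFromPanel(panel, panels)
  trait <- buildTrait(qd, h2, seed = seed + 2)
  pop <- randomMatingPhase(panel, panels, nMales, nFemales, nOffspring,
                           nGenerations, trait, seed = seed + 3)
  list(panel = panel, panels = panels, trait = trait, pop = pop)
}

qtlDosagesFromPanel <- function(panel, panels) {
  h <- haplotypes(panel)
  n <- nIndiv(panel)
  h[panels@qtlIdx, seq(1, 2 * n, 2), drop = FALSE] +
    h[panels@qtlIdx, seq(2, 2 * n, 2), drop = FALSE]
}

# hand-built population: founders with prescribed haplotypes, no offspring
manualFounders <- function(alleles, map, sexes = NULL,
                           qtlIdx = integer(0)) {
  nF <- ncol(alleles) %/% 2
  if (is.null(sexes)) sexes <- rep(c(1L, 2L), length.out = nF)
  S <- nrow(alleles)
  labels <- matrix(rep(seq_len(2L * nF), each = S), nrow = S)
  storage.mode(labels) <- "integer"
  storage.mode(alleles) <- "integer"
  panels <- new("LociPanels",
                snpIdx = setdiff(seq_len(S), qtlIdx),
                neutralIdx = integer(0), qtlIdx = as.integer(qtlIdx))
  new("Population",
      ped = data.frame(id = seq_len(nF), sire = 0L, dam = 0L,
                       sex = as.integer(sexes), generation = 0L),
      alleles = alleles, labels = labels, map = map, panels = panels,
      tbv = rep(0, nF), phenotype = rep(NA_real_, nF))
}

# append one offspring with prescribed gametes (for exact-value tests)
addChild <- function(pop, sire, dam, patAlleles, patLabels, matAlleles,
                     matLabels, generation = 1L, sex = 1L) {
  ped <- rbind(pop@ped,
               data.frame(id = nrow(pop@ped) + 1L, sire = as.integer(sire),
                          dam = as.integer(dam), sex = as.integer(sex),
                          generation = as.integer(generation)))
  new("Population", ped = ped,
      alleles = cbind(pop@alleles, as.integer(patAlleles),
                      as.integer(matAlleles)),
      labels = cbind(pop@labels, as.integer(patLabels),
                     as.integer(matLabels)),
      map = pop@map, panels = pop@panels,
      tbv = c(pop@tbv, 0), phenotype = c(pop@phenotype, NA_real_))
}

# naive O(S) run scan used as the independent oracle for segment detection
naiveSegments <- function(hapA, hapB, map, minSnps, minLenCm) {
  out <- NULL
  for (cc in unique(map@chrom)) {
    idx <- which(map@chrom == cc)
    eq <- hapA[idx] == hapB[idx]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i <- idx[starts[k]]; j <- idx[ends[k]]
      n <- j - i + 1
      span <- map@posCm[j] - map@posCm[i]
      if (n >= minSnps && span >= minLenCm)
        out <- rbind(out, data.frame(chrom = cc, startCm = map@posCm[i],
                                     endCm = map@posCm[j], nSnps = n))
    }
  }
  if (is.null(out))
    data.frame(chrom = numeric(0), startCm = numeric(0),
               endCm = numeric(0), nSnps = numeric(0))
  else out
}

computeTbvOracle <- function(d, a) as.vector(t(d) %*% a)

# reduced scheme configuration for pipeline tests
smallConfig <- function(scheme = "IBD", seed = 1, nSelect = 3, dF = 0.01,
                        ...) {
  schemeConfig(scheme = scheme, dF = dF, nSelectGenerations = nSelect,
               genome = list(nChrom = 3, chromCm = 60, nSnp = 500,
                             nNeutral = 150, nQtl = 80, ne = 60,
                             nSites = 5000, burninGenerations = 600),
               base = list(nMales = 15, nFemales = 15, nOffspring = 60,
                           nRandomGenerations = 3),
               seed = seed, ...)
}

# two-chromosome map with S roughly evenly spread loci
mapOfRel <- function(S, chromLen = 100) {
  half <- ceiling(S / 2)
  rest <- S - half
  geneticMap(c(rep(1L, half), rep(2L, rest)),
             c(seq(1, 99, length.out = half),
               seq(1, 99, length.out = rest)),
             c(chromLen, chromLen))
}

# kinship recurrence for a dioecious population with fixed breeding pools:
# expected mean inbreeding of the cohort born in generation t
expectedFRecurrence <- function(nMales, nFemales, nGenerations) {
  cc <- 1 / (4 * nMales) + 1 / (4 * nFemales)
  theta <- 0; f <- 0
  for (t in seq_len(nGenerations)) {
    thetaNew <- theta + cc * ((1 + f) / 2 - theta)
    f <- theta
    theta <- thetaNew
  }
  f
}
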