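# Stage-specific seeds derived deterministically from the replicate seed so
# that matrix construction cannot perturb the shared simulation stream.
stageSeed <- function(seed, stage, generation = 0L) {
  as.integer((as.numeric(seed) * 48271 + stage * 100003 + generation * 7919) %%
               2147483647)
}

#' Neutral Wright-Fisher burn-in of the historic population
#'
#' Simulates a constant-size random-mating population forward in time with
#' Haldane (Poisson) recombination and infinite-alleles mutation at uniformly
#' placed candidate sites, starting from a monomorphic state.  Monomorphic
#' sites are dropped; polymorphic sites are recoded biallelic (the most
#' frequent allele versus the rest) and returned as the historic haplotype
#' panel from which founders and locus panels are sampled.
#'
#' @param ne effective (= census) number of diploid individuals.
#' @param map a \linkS4class{GeneticMap} fixing chromosome number and lengths
#'   (its loci, if any, are ignored); see \code{\link{genomeMap}}.
#' @param nSites number of candidate mutation sites placed uniformly along
#'   the genome.
#' @param mu per-site, per-gamete, per-generation mutation rate.
#' @param nGenerations number of burn-in generations (10 * ne is a common
#'   choice for approximate mutation-drift equilibrium).
#' @param seed optional integer seed.
#' @return a \linkS4class{HaplotypePanel} of \code{2 * ne} phased haplotypes.
#' @export
wfBurnIn <- function(ne, map, nSites, mu, nGenerations, seed = NULL) {
  if (ne < 2) stop("ne must be at least 2")
  if (nGenerations < 0) stop("nGenerations must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  lens <- chromLengths(map)
  chromIdx <- sample.int(length(lens), nSites, replace = TRUE,
                         prob = lens / sum(lens))
  pos <- runif(nSites) * lens[chromIdx]
  o <- order(chromIdx, pos)
  chromIdx <- chromIdx[o]
  pos <- pos[o]
  labs <- cpp_wf_burnin(ne, nGenerations, as.integer(chromIdx), pos, lens, mu)
  coll <- cpp_collapse_biallelic(labs)
  if (length(coll$idx) == 0L)
    stop("empty panel: no polymorphic biallelic sites after burn-in")
  new("HaplotypePanel",
      haplotypes = coll$alleles,
      map = geneticMap(chromIdx[coll$idx], pos[coll$idx], lens),
      freq = coll$freq,
      nSitesSimulated = as.integer(nSites))
}

#' Sample disjoint SNP, neutral-locus and QTL panels
#'
#' Draws three disjoint sets of sites with minor allele frequency above
#' \code{mafMin} from a historic panel, mirroring the random sampling of a
#' SNP chip, a monitoring set of neutral loci, and the QTL of the trait.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param nSnp,nNeutral,nQtl panel sizes.
#' @param mafMin minimum minor allele frequency (exclusive).
#' @param seed optional integer seed.
#' @return a \linkS4class{LociPanels}.
#' @export
sampleLociPanels <- function(panel, nSnp, nNeutral, nQtl, mafMin = 0.01,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  maf <- pmin(panel@freq, 1 - panel@freq)
  eligible <- which(maf > mafMin)
  need <- nSnp + nNeutral + nQtl
  if (length(eligible) < need)
    stop(sprintf(
      "insufficient eligible sites: need %d with MAF > %g, have %d (shortfall %d)",
      need, mafMin, length(eligible), need - length(eligible)))
  pick <- sample(eligible, need)
  new("LociPanels",
      snpIdx = sort(pick[seq_len(nSnp)]),
      neutralIdx = sort(pick[nSnp + seq_len(nNeutral)]),
      qtlIdx = sort(pick[nSnp + nNeutral + seq_len(nQtl)]))
}

#' Build the additive trait architecture
#'
#' QTL effects are sampled from a standard normal distribution (unless
#' supplied) and rescaled so that the true breeding values of the supplied
#' founder-era individuals have unit variance; the residual variance is then
#' \eqn{(1 - h^2) / h^2} so that the trait has the requested heritability.
#'
#' @param qtlDosages QTL x individuals matrix of 0/1/2 dosages.
#' @param h2 narrow-sense heritability.
#' @param seed optional integer seed.
#' @param effects optional unscaled effects (otherwise sampled N(0, 1)).
#' @return a \linkS4class{TraitArchitecture}.
#' @export
buildTrait <- function(qtlDosages, h2, seed = NULL, effects = NULL) {
  if (ncol(qtlDosages) < 2) stop("at least 2 individuals required")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(effects)) effects <- rnorm(nrow(qtlDosages))
  raw <- as.vector(crossprod(qtlDosages, effects))
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0)
    stop("scaling error: zero TBV variance (constant QTL dosages)")
  a <- effects / s
  new("TraitArchitecture", qtlEffects = a, h2 = h2,
      sigmaE2 = (1 - h2) / h2)
}

computeTbv <- function(qtlDosages, trait) {
  as.vector(crossprod(qtlDosages, trait@qtlEffects))
}

#' Simulate one meiosis
#'
#' Draws a gamete from one individual: per chromosome, a Poisson (Haldane)
#' number of crossovers at uniform positions, a fair-coin starting
#' haplotype, and identical breakpoints applied to the allele and the
#' founder-label tracks.
#'
#' @param pop a \linkS4class{Population}.
#' @param individual individual id.
#' @param seed optional integer seed.
#' @return list with integer vectors \code{alleles} and \code{labels}.
#' @export
simulateMeiosis <- function(pop, individual, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- cpp_make_gametes(pop@alleles, pop@labels, as.integer(individual),
                        pop@map@chrom, pop@map@posCm,
                        pop@map@chromLengths)
  list(alleles = as.vector(g$alleles), labels = as.vector(g$labels))
}

# ---- growth buffer ---------------------------------------------------------
# Preallocated haplotype storage used by the breeding loops so that adding a
# generation never reallocates the accumulated history (which would trigger
# repeated large allocations and GC churn).  The buffer is an environment;
# cpp_write_cols() fills its matrices in place.

newBuffer <- function(pop, extraIndiv) {
  e <- new.env(parent = emptyenv())
  n <- nIndiv(pop)
  cap <- n + extraIndiv
  e$alleles <- matrix(0L, nLoci(pop), 2L * cap)
  e$labels <- matrix(0L, nLoci(pop), 2L * cap)
  cpp_write_cols(e$alleles, 1L, pop@alleles)
  cpp_write_cols(e$labels, 1L, pop@labels)
  pad <- function(x, fill) c(x, rep(fill, extraIndiv))
  e$sire <- pad(pop@ped$sire, 0L)
  e$dam <- pad(pop@ped$dam, 0L)
  e$sex <- pad(pop@ped$sex, 0L)
  e$generation <- pad(pop@ped$generation, -1L)
  e$tbv <- pad(pop@tbv, NA_real_)
  e$phenotype <- pad(pop@phenotype, NA_real_)
  e$n <- n
  e$map <- pop@map
  e$panels <- pop@panels
  e
}

bufAppend <- function(e, sires, dams, generation, trait) {
  k <- length(sires)
  pat <- cpp_make_gametes(e$alleles, e$labels, as.integer(sires),
                          e$map@chrom, e$map@posCm, e$map@chromLengths)
  mat <- cpp_make_gametes(e$alleles, e$labels, as.integer(dams),
                          e$map@chrom, e$map@posCm, e$map@chromLengths)
  S <- nrow(e$alleles)
  newA <- matrix(0L, S, 2L * k)
  newL <- matrix(0L, S, 2L * k)
  odd <- seq(1L, 2L * k, 2L)
  newA[, odd] <- pat$alleles; newA[, odd + 1L] <- mat$alleles
  newL[, odd] <- pat$labels; newL[, odd + 1L] <- mat$labels
  cpp_write_cols(e$alleles, 2L * e$n + 1L, newA)
  cpp_write_cols(e$labels, 2L * e$n + 1L, newL)
  idx <- e$n + seq_len(k)
  e$sire[idx] <- as.integer(sires)
  e$dam[idx] <- as.integer(dams)
  e$sex[idx] <- sample(c(1L, 2L), k, replace = TRUE)
  e$generation[idx] <- as.integer(generation)
  qd <- newA[e$panels@qtlIdx, odd, drop = FALSE] +
    newA[e$panels@qtlIdx, odd + 1L, drop = FALSE]
  e$tbv[idx] <- computeTbv(qd, trait)
  e$phenotype[idx] <- NA_real_
  e$n <- e$n + k
  invisible(e)
}

bufMaterialize <- function(e) {
  n <- e$n
  used <- seq_len(2L * n)
  new("Population",
      ped = data.frame(id = seq_len(n), sire = e$sire[seq_len(n)],
                       dam = e$dam[seq_len(n)], sex = e$sex[seq_len(n)],
                       generation = e$generation[seq_len(n)]),
      alleles = if (2L * n == ncol(e$alleles)) e$alleles else
        e$alleles[, used, drop = FALSE],
      labels = if (2L * n == ncol(e$labels)) e$labels else
        e$labels[, used, drop = FALSE],
      map = e$map, panels = e$panels,
      tbv = e$tbv[seq_len(n)], phenotype = e$phenotype[seq_len(n)])
}

# detached view of a subset of individuals (pedigree links zeroed; local ids)
bufView <- function(e, individuals) {
  cols <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  k <- length(individuals)
  new("Population",
      ped = data.frame(id = seq_len(k), sire = 0L, dam = 0L,
                       sex = e$sex[individuals],
                       generation = e$generation[individuals]),
      alleles = e$alleles[, cols, drop = FALSE],
      labels = e$labels[, cols, drop = FALSE],
      map = e$map, panels = e$panels,
      tbv = e$tbv[individuals], phenotype = e$phenotype[individuals])
}

bufCohort <- function(e, generation) {
  which(e$generation[seq_len(e$n)] == generation)
}

# Append offspring from given sire/dam id vectors (one mating per offspring).
makeOffspring <- function(pop, sires, dams, generation, trait) {
  n <- length(sires)
  pat <- cpp_make_gametes(pop@alleles, pop@labels, as.integer(sires),
                          pop@map@chrom, pop@map@posCm, pop@map@chromLengths)
  mat <- cpp_make_gametes(pop@alleles, pop@labels, as.integer(dams),
                          pop@map@chrom, pop@map@posCm, pop@map@chromLengths)
  S <- nLoci(pop)
  newA <- matrix(0L, S, 2L * n)
  newL <- matrix(0L, S, 2L * n)
  newA[, seq(1L, 2L * n, by = 2L)] <- pat$alleles
  newA[, seq(2L, 2L * n, by = 2L)] <- mat$alleles
  newL[, seq(1L, 2L * n, by = 2L)] <- pat$labels
  newL[, seq(2L, 2L * n, by = 2L)] <- mat$labels
  sex <- sample(c(1L, 2L), n, replace = TRUE)
  id0 <- nIndiv(pop)
  ped <- rbind(pop@ped,
               data.frame(id = id0 + seq_len(n), sire = as.integer(sires),
                          dam = as.integer(dams), sex = sex,
                          generation = as.integer(generation)))
  qd <- newA[pop@panels@qtlIdx, seq(1L, 2L * n, by = 2L), drop = FALSE] +
    newA[pop@panels@qtlIdx, seq(2L, 2L * n, by = 2L), drop = FALSE]
  new("Population", ped = ped,
      alleles = cpp_cbind_int(pop@alleles, newA),
      labels = cpp_cbind_int(pop@labels, newL),
      map = pop@map, panels = pop@panels,
      tbv = c(pop@tbv, computeTbv(qd, trait)),
      phenotype = c(pop@phenotype, rep(NA_real_, n)))
}

#' Found and randomly mate the base-building population
#'
#' Samples founders (distinct haplotype pairs, without replacement) from the
#' historic panel, gives every founder two globally unique founder-origin
#' labels, and then mates at random for \code{nGenerations} generations.
#' Each generation a breeding pool of \code{nMales} males and
#' \code{nFemales} females is drawn at random from the previous cohort
#' (the founders are the first pool); every offspring then draws its sire
#' and dam uniformly from the pool, with replacement, and its sex by a fair
#' coin.  The pool sizes fix the rate of inbreeding at approximately
#' \eqn{1/(8 N_m) + 1/(8 N_f)} per generation.  No new mutations occur
#' during this or any later phase.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param panels a \linkS4class{LociPanels} indexing the panel's sites.
#' @param nMales,nFemales founder counts by sex.
#' @param nOffspring offspring per generation.
#' @param nGenerations random-mating generations (0 returns the founders).
#' @param trait a \linkS4class{TraitArchitecture}.
#' @param seed optional integer seed.
#' @return a \linkS4class{Population} holding founders (generation 0) and all
#'   random-mating generations.
#' @export
randomMatingPhase <- function(panel, panels, nMales, nFemales, nOffspring,
                              nGenerations, trait, seed = NULL) {
  if (nMales < 1 || nFemales < 1)
    stop("configuration error: both sexes must be represented among founders")
  if (nGenerations > 0 && nOffspring < 2)
    stop("configuration error: nOffspring must be at least 2")
  nF <- nMales + nFemales
  if (nIndiv(panel) < nF)
    stop("panel provides fewer individuals than requested founders")
  if (!is.null(seed)) set.seed(seed)
  pickInd <- sample.int(nIndiv(panel), nF)
  cols <- as.vector(rbind(2L * pickInd - 1L, 2L * pickInd))
  alleles <- panel@haplotypes[, cols, drop = FALSE]
  labels <- matrix(rep(seq_len(2L * nF), each = nrow(alleles)),
                   nrow = nrow(alleles))
  storage.mode(labels) <- "integer"
  sex <- sample(c(rep(1L, nMales), rep(2L, nFemales)))
  ped <- data.frame(id = seq_len(nF), sire = 0L, dam = 0L, sex = sex,
                    generation = 0L)
  qd <- alleles[panels@qtlIdx, seq(1L, 2L * nF, by = 2L), drop = FALSE] +
    alleles[panels@qtlIdx, seq(2L, 2L * nF, by = 2L), drop = FALSE]
  pop <- new("Population", ped = ped, alleles = alleles, labels = labels,
             map = panel@map, panels = panels,
             tbv = computeTbv(qd, trait),
             phenotype = rep(NA_real_, nF))
  if (nGenerations == 0) return(pop)
  e <- newBuffer(pop, nOffspring * nGenerations)
  for (g in seq_len(nGenerations)) {
    prev <- bufCohort(e, g - 1L)
    males <- prev[e$sex[prev] == 1L]
    females <- prev[e$sex[prev] == 2L]
    if (length(males) < nMales || length(females) < nFemales)
      stop(sprintf(
        "configuration error: generation %d has too few males or females for the breeding pool",
        g - 1L))
    poolM <- males[sample.int(length(males), nMales)]
    poolF <- females[sample.int(length(females), nFemales)]
    sires <- poolM[sample.int(nMales, nOffspring, replace = TRUE)]
    dams <- poolF[sample.int(nFemales, nOffspring, replace = TRUE)]
    bufAppend(e, sires, dams, g, trait)
  }
  bufMaterialize(e)
}

#' Assign phenotypes
#'
#' \eqn{y_j = TBV_j + e_j} with independent normal residuals of variance
#' \code{trait@sigmaE2}.
#'
#' @param pop a \linkS4class{Population}.
#' @param trait a \linkS4class{TraitArchitecture}.
#' @param which ids to phenotype (default: all not yet phenotyped).
#' @param seed optional integer seed.
#' @return the Population with phenotypes filled in.
#' @export
assignPhenotypes <- function(pop, trait, which = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(which)) which <- pop@ped$id[is.na(pop@phenotype)]
  pop@phenotype[which] <- pop@tbv[which] +
    rnorm(length(which), 0, sqrt(trait@sigmaE2))
  pop
}
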