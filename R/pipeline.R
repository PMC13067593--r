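schemeTags <- c("IBD_FULL", "IBD", "VR_BF", "VR_CF", "FGLA",
                "ROH01", "ROH05", "ROH08", "ROH10")

rohMinLen <- c(ROH01 = 1, ROH05 = 5, ROH08 = 8, ROH10 = 10)

#' Configure a selection scheme
#'
#' Desk-scale defaults: 3 chromosomes of 100 cM, panels of 3,000 SNPs,
#' 1,000 neutral loci and 500 QTL (MAF > 1\%), a burn-in population of
#' ne = 200 run for 10 ne generations, 100 + 100 founders producing 400
#' offspring for 10 random-mating generations, heritability 0.25, and 10
#' generations of GBLUP + OCS at a 0.5\% per-generation inbreeding target.
#' The scheme tag names the matrix used to constrain inbreeding; EBVs always
#' come from GBLUP with the base-frequency VanRaden matrix except for
#' IBD_FULL, which uses the true IBD matrix throughout.
#'
#' @param scheme one of IBD_FULL, IBD, VR_BF, VR_CF, FGLA, ROH01, ROH05,
#'   ROH08, ROH10.
#' @param dF target rate of inbreeding per generation.
#' @param nSelectGenerations OCS generations.
#' @param genome,base,trait named lists overriding individual defaults.
#' @param minRohSnps minimum SNPs per ROH segment.
#' @param refFreqSource reference frequencies for the VR_BF constraint
#'   matrix: "base" (OCS base generation) or "founders".
#' @param fglaBase gene-dropping base for the FGLA matrix: "base" or
#'   "founders".
#' @param seed replicate seed.
#' @param keepPopulation retain the full Population in the result.
#' @return a validated configuration list.
#' @export
schemeConfig <- function(scheme = "IBD", dF = 0.005, nSelectGenerations = 10,
                         genome = list(), base = list(), trait = list(),
                         minRohSnps = 20, refFreqSource = "base",
                         fglaBase = "base", seed = 1L,
                         keepPopulation = TRUE) {
  scheme <- match.arg(scheme, schemeTags)
  g <- utils::modifyList(list(nChrom = 3L, chromCm = 100, nSnp = 3000L,
                              nNeutral = 1000L, nQtl = 500L, mafMin = 0.01,
                              mu = 2.5e-4, nSites = 15000L, ne = 200L,
                              burninGenerations = 2000L), genome)
  b <- utils::modifyList(list(nMales = 100L, nFemales = 100L,
                              nOffspring = 400L,
                              nRandomGenerations = 10L), base)
  tr <- utils::modifyList(list(h2 = 0.25), trait)
  if (dF < 0 || dF >= 1) stop("dF must be in [0, 1)")
  list(scheme = scheme, dF = dF,
       nSelectGenerations = as.integer(nSelectGenerations),
       genome = g, base = b, trait = tr,
       minRohSnps = as.integer(minRohSnps),
       refFreqSource = match.arg(refFreqSource, c("base", "founders")),
       fglaBase = match.arg(fglaBase, c("base", "founders")),
       seed = as.integer(seed), keepPopulation = isTRUE(keepPopulation))
}

# constraint matrix among the candidate cohort, per scheme tag
constraintMatrix <- function(config, pop, candidates, baseFreqsSnp,
                             founderFreqsSnp, baseGen, generation) {
  tag <- config$scheme
  if (tag %in% c("IBD", "IBD_FULL"))
    return(gTrueIbd(pop, individuals = candidates))
  if (tag == "VR_BF") {
    p <- if (config$refFreqSource == "founders") founderFreqsSnp else
      baseFreqsSnp
    return(gVanRaden(dosages(pop, individuals = candidates,
                             loci = pop@panels@snpIdx),
                     p, ids = candidates, method = "VR_BF"))
  }
  if (tag == "VR_CF") {
    # loci fixed in the cohort centre to zero and get zero weight; only a
    # fully monomorphic cohort would break the denominator
    p <- alleleFreqs(pop, individuals = candidates,
                     loci = pop@panels@snpIdx)
    return(gVanRaden(dosages(pop, individuals = candidates,
                             loci = pop@panels@snpIdx),
                     p, ids = candidates, method = "VR_CF"))
  }
  if (tag == "FGLA") {
    bg <- if (config$fglaBase == "founders") 0L else baseGen
    ind <- inferSegregationIndicators(
      pop, baseGeneration = bg,
      seed = stageSeed(config$seed, 6L, generation))
    return(gFgla(pop, ind, individuals = candidates))
  }
  minLen <- rohMinLen[[tag]]
  segs <- collectPopulationSegments(pop, individuals = candidates,
                                    minSnps = config$minRohSnps,
                                    minLenCm = minLen)
  gRoh(segs, minLenCm = minLen)
}

cohortIds <- function(pop, generation) {
  pop@ped$id[pop@ped$generation == generation]
}

reportRow <- function(pop, trait, generation, phase, ref, sol = NULL,
                      C = NA_real_, meanEbv = NA_real_) {
  ids <- cohortIds(pop, generation)
  qN <- alleleFreqs(pop, individuals = ids, loci = pop@panels@neutralIdx)
  qS <- alleleFreqs(pop, individuals = ids, loci = pop@panels@snpIdx)
  qQ <- alleleFreqs(pop, individuals = ids, loci = pop@panels@qtlIdx)
  fdN <- fDrift(ref$qNeutral, qN)
  fdS <- fDrift(ref$qSnp, qS)
  fhN <- fHom(2 * ref$qNeutral * (1 - ref$qNeutral),
              observedHet(pop, ids, pop@panels@neutralIdx))
  fhS <- fHom(2 * ref$qSnp * (1 - ref$qSnp),
              observedHet(pop, ids, pop@panels@snpIdx))
  fx <- qtlFixationCounts(ref$qQtl, qQ)
  data.frame(
    generation = generation, phase = phase, n = length(ids),
    meanFIbd = mean(ibdInbreeding(pop, individuals = ids)),
    fDriftNeutral = fdN$mean, fHomNeutral = fhN$mean,
    fDriftSnp = fdS$mean, fHomSnp = fhS$mean,
    genicVar = genicVariance(qQ, trait@qtlEffects),
    tbvVar = tbvVariance(pop@tbv[ids]),
    meanTbv = mean(pop@tbv[ids]), meanEbv = meanEbv,
    nParents = if (is.null(sol)) NA_integer_ else sol@nSelected,
    qtlFixed = unname(fx["fixed"]), qtlLost = unname(fx["lost"]),
    constraintC = C,
    achievedCoancestry = if (is.null(sol)) NA_real_ else sol@coancestry,
    feasible = if (is.null(sol)) NA else sol@feasible)
}

refFreqs <- function(pop, generation) {
  ids <- cohortIds(pop, generation)
  list(qNeutral = alleleFreqs(pop, ids, loci = pop@panels@neutralIdx),
       qSnp = alleleFreqs(pop, ids, loci = pop@panels@snpIdx),
       qQtl = alleleFreqs(pop, ids, loci = pop@panels@qtlIdx))
}

#' Run one selection-scheme replicate
#'
#' Executes the full pipeline: Wright-Fisher burn-in, panel sampling, trait
#' construction, founder labelling, random mating to the OCS base, then per
#' selection generation phenotyping, GBLUP (base-frequency VanRaden, or true
#' IBD for IBD_FULL, over all animals born since the base), the scheme's
#' constraint matrix, OCS at the cumulative coancestry bound
#' \eqn{C_t = 1 - (1 - F_0)(1 - \Delta F)^t}, random matings proportional to
#' the optimal contributions, and Poisson-recombination meiosis.  Diversity
#' diagnostics in the random phase are referenced to the founders, those in
#' the selection phase to the OCS base generation.
#'
#' @param config from \code{\link{schemeConfig}}.
#' @return a \linkS4class{SchemeResult}.
#' @export
runScheme <- function(config) {
  g <- config$genome
  b <- config$base
  map <- genomeMap(g$nChrom, g$chromCm)
  panel <- wfBurnIn(g$ne, map, g$nSites, g$mu, g$burninGenerations,
                    seed = stageSeed(config$seed, 1L))
  panels <- sampleLociPanels(panel, g$nSnp, g$nNeutral, g$nQtl, g$mafMin,
                             seed = stageSeed(config$seed, 2L))
  qd <- haplotypes(panel)[panels@qtlIdx, seq(1, 2 * nIndiv(panel), by = 2),
                          drop = FALSE] +
    haplotypes(panel)[panels@qtlIdx, seq(2, 2 * nIndiv(panel), by = 2),
                      drop = FALSE]
  trait <- buildTrait(qd, config$trait$h2,
                      seed = stageSeed(config$seed, 3L))
  pop <- randomMatingPhase(panel, panels, b$nMales, b$nFemales,
                           b$nOffspring, b$nRandomGenerations, trait,
                           seed = stageSeed(config$seed, 4L))
  baseGen <- b$nRandomGenerations
  founderRef <- refFreqs(pop, 0L)
  baseRef <- refFreqs(pop, baseGen)
  founderFreqsSnp <- founderRef$qSnp
  baseFreqsSnp <- baseRef$qSnp
  e <- newBuffer(pop, b$nOffspring * config$nSelectGenerations)
  rm(pop)
  genRow <- function(gg, phase, ref, ...) {
    v <- bufView(e, bufCohort(e, gg))
    row <- reportRow(v, trait, gg, phase, ref, ...)
    row
  }
  report <- do.call(rbind, lapply(0:baseGen, function(gg)
    genRow(gg, "random", founderRef)))
  contribs <- list()
  if (config$nSelectGenerations > 0) {
    # base coancestry as seen by the scheme's own constraint matrix
    needsPedigree <- config$scheme == "FGLA"
    schemeA <- function(candidates, generation) {
      if (needsPedigree) {
        constraintMatrix(config, bufMaterialize(e), candidates,
                         baseFreqsSnp, founderFreqsSnp, baseGen, generation)
      } else {
        v <- bufView(e, candidates)
        constraintMatrix(config, v, seq_along(candidates),
                         baseFreqsSnp, founderFreqsSnp, baseGen, generation)
      }
    }
    A0 <- schemeA(bufCohort(e, baseGen), baseGen)
    F0 <- mean(relValues(A0)) / 2
    ebvRef <- if (config$refFreqSource == "founders") founderFreqsSnp else
      baseFreqsSnp
    Zcum <- NULL       # centred SNP dosages of all animals since base
    Gcum <- NULL       # their VanRaden base-frequency matrix, grown blockwise
    vrDenom <- 2 * sum(ebvRef * (1 - ebvRef))
    gblupIds <- integer(0)
    for (t in seq_len(config$nSelectGenerations)) {
      gen <- baseGen + t
      newcoh <- bufCohort(e, gen - 1L)
      set.seed(stageSeed(config$seed, 5L, gen))
      e$phenotype[newcoh] <- e$tbv[newcoh] +
        rnorm(length(newcoh), 0, sqrt(trait@sigmaE2))
      gblupIds <- c(gblupIds, newcoh)
      if (config$scheme == "IBD_FULL") {
        Gebv <- relValues(gTrueIbd(bufView(e, gblupIds)))
      } else {
        Znew <- dosages(bufView(e, newcoh), loci = e$panels@snpIdx) -
          2 * ebvRef
        if (is.null(Zcum)) {
          Zcum <- Znew
          Gcum <- crossprod(Znew) / vrDenom
        } else {
          B <- crossprod(Zcum, Znew) / vrDenom
          Gcum <- rbind(cbind(Gcum, B),
                        cbind(t(B), crossprod(Znew) / vrDenom))
          Zcum <- cbind(Zcum, Znew)
        }
        Gebv <- Gcum
      }
      ebv <- gblupEbv(Gebv, e$phenotype[gblupIds], config$trait$h2)
      cand <- newcoh
      candEbv <- ebv[match(cand, gblupIds)]
      A <- schemeA(cand, gen)
      Ct <- coancestryConstraint(F0, config$dF, t)
      sol <- ocsOptimize(candEbv, A, e$sex[cand], Ct, ids = cand)
      m <- sampleMatings(sol, b$nOffspring,
                         seed = stageSeed(config$seed, 7L, gen))
      bufAppend(e, m$sire, m$dam, gen, trait)
      contribs[[t]] <- data.frame(generation = gen, id = cand,
                                  sex = e$sex[cand], ebv = candEbv,
                                  contribution = sol@contributions)
      report <- rbind(report,
                      genRow(gen, "selection", baseRef, sol = sol, C = Ct,
                             meanEbv = mean(candEbv)))
    }
  }
  new("SchemeResult", report = report,
      contributions = if (length(contribs)) do.call(rbind, contribs) else
        data.frame(),
      config = config, seed = config$seed,
      population = if (config$keepPopulation) bufMaterialize(e) else NULL)
}

#' Run replicates of a scheme and aggregate
#'
#' Replicate seeds are derived deterministically from \code{baseSeed}; the
#' per-generation report rows are stacked, summarized as across-replicate
#' means and standard errors, and the realized rate of true-IBD inbreeding
#' is estimated per replicate as the slope of \eqn{-\log(1 - F_{IBD,t})} on
#' generation, over the whole series and over the selection phase alone.
#'
#' @param config from \code{\link{schemeConfig}}.
#' @param nRep number of replicates.
#' @param baseSeed master seed.
#' @param keepPopulations retain each replicate's Population.
#' @return list with \code{reports}, \code{summary} and \code{deltaF}.
#' @export
runReplicates <- function(config, nRep, baseSeed = 1L,
                          keepPopulations = FALSE) {
  results <- vector("list", nRep)
  for (r in seq_len(nRep)) {
    cfg <- config
    cfg$seed <- stageSeed(baseSeed, 999L, r)
    cfg$keepPopulation <- keepPopulations
    results[[r]] <- runScheme(cfg)
  }
  reports <- do.call(rbind, lapply(seq_len(nRep), function(r)
    cbind(rep = r, results[[r]]@report)))
  num <- vapply(reports, is.numeric, logical(1))
  dt <- data.table::as.data.table(reports[, num])
  summ <- as.data.frame(dt[, c(lapply(.SD, mean),
                               list(seTbv = stats::sd(meanTbv) /
                                      sqrt(.N))),
                           by = "generation"])
  baseGen <- config$base$nRandomGenerations
  deltaF <- do.call(rbind, lapply(seq_len(nRep), function(r) {
    rep_ <- results[[r]]@report
    selRows <- rep_$generation >= baseGen
    data.frame(
      rep = r,
      slopeAll = deltaFSlope(rep_$meanFIbd,
                             rep_$generation)$slope,
      slopeSelection = deltaFSlope(rep_$meanFIbd[selRows],
                                   rep_$generation[selRows])$slope)
  }))
  list(reports = reports, summary = summ, deltaF = deltaF,
       results = if (keepPopulations) results else NULL)
}

#' Matrix-agreement table against true IBD
#'
#' For the cohort of one generation (or pooled over generations), builds the
#' requested relationship matrices and regresses each on the true IBD
#' matrix, separately for inbreeding (diagonals) and coancestry
#' (off-diagonals).
#'
#' @param pop a \linkS4class{Population} from an IBD-constrained run.
#' @param baseGeneration OCS base generation (reference frequencies, FGLA
#'   base).
#' @param generations cohort generation(s); rows are pooled when several are
#'   given.
#' @param methods matrix tags to include.
#' @param minRohSnps minimum SNPs per ROH segment.
#' @return data.frame in the layout intercept / slope / SE / correlation /
#'   CCC by method and element set.
#' @export
compareTable <- function(pop, baseGeneration, generations,
                         methods = c("VR_BF", "VR_CF", "FGLA",
                                     "ROH01", "ROH05", "ROH08", "ROH10"),
                         minRohSnps = 20) {
  baseFreqs <- alleleFreqs(pop, cohortIds(pop, baseGeneration),
                           loci = pop@panels@snpIdx)
  acc <- list()
  for (gg in generations) {
    ids <- cohortIds(pop, gg)
    truth <- gTrueIbd(pop, individuals = ids)
    for (m in methods) {
      est <- switch(substr(m, 1, 3),
        VR_ = {
          p <- if (m == "VR_BF") baseFreqs else
            alleleFreqs(pop, ids, loci = pop@panels@snpIdx)
          gVanRaden(dosages(pop, individuals = ids,
                            loci = pop@panels@snpIdx), p, ids = ids,
                    method = m)
        },
        FGL = {
          ind <- inferSegregationIndicators(pop,
                                            baseGeneration = baseGeneration)
          gFgla(pop, ind, individuals = ids)
        },
        ROH = {
          len <- rohMinLen[[m]]
          gRoh(collectPopulationSegments(pop, individuals = ids,
                                         minSnps = minRohSnps,
                                         minLenCm = len), minLenCm = len)
        })
      acc[[paste(m, gg)]] <- list(method = m,
                                  dT = diag(relValues(truth)),
                                  dE = diag(relValues(est)),
                                  oT = relValues(truth)[upper.tri(relValues(truth))],
                                  oE = relValues(est)[upper.tri(relValues(est))])
    }
  }
  one <- function(x, y, m, set) {
    cbind(method = m, set = set, regRow(x, y))
  }
  out <- do.call(rbind, lapply(unique(vapply(acc, `[[`, "", "method")),
    function(m) {
      sel <- acc[vapply(acc, `[[`, "", "method") == m]
      dT <- unlist(lapply(sel, `[[`, "dT"))
      dE <- unlist(lapply(sel, `[[`, "dE"))
      oT <- unlist(lapply(sel, `[[`, "oT"))
      oE <- unlist(lapply(sel, `[[`, "oE"))
      rbind(one(dT, dE, m, "diagonal"), one(oT, oE, m, "offdiagonal"))
    }))
  rownames(out) <- NULL
  out
}

#' Rate-of-inbreeding table across relationship matrices
#'
#' For one population, computes the mean coancestry
#' (mean off-diagonal relationship / 2) of every requested matrix at every
#' generation and regresses \eqn{-\log(1 - f_t)} on generation.
#'
#' @param pop a \linkS4class{Population}.
#' @param generations generations to include.
#' @param baseGeneration reference generation for VR_BF frequencies and the
#'   FGLA base (the founders for a whole-series comparison).
#' @param methods matrix tags (IBD always included).
#' @param minRohSnps minimum SNPs per ROH segment.
#' @return data.frame with method and deltaF columns.
#' @export
deltaFTable <- function(pop, generations, baseGeneration = 0L,
                        methods = c("VR_BF", "VR_CF", "FGLA",
                                    "ROH01", "ROH05", "ROH08", "ROH10"),
                        minRohSnps = 20) {
  methods <- unique(c("IBD", methods))
  baseFreqs <- alleleFreqs(pop, cohortIds(pop, baseGeneration),
                           loci = pop@panels@snpIdx)
  fglaInd <- if ("FGLA" %in% methods)
    inferSegregationIndicators(pop, baseGeneration = baseGeneration) else NULL
  f <- matrix(NA_real_, length(generations), length(methods),
              dimnames = list(NULL, methods))
  for (k in seq_along(generations)) {
    ids <- cohortIds(pop, generations[k])
    for (m in methods) {
      G <- switch(substr(m, 1, 3),
        IBD = gTrueIbd(pop, individuals = ids),
        VR_ = {
          p <- if (m == "VR_BF") baseFreqs else
            alleleFreqs(pop, ids, loci = pop@panels@snpIdx)
          gVanRaden(dosages(pop, individuals = ids,
                            loci = pop@panels@snpIdx), p, ids = ids,
                    method = m)
        },
        FGL = gFgla(pop, fglaInd, individuals = ids),
        ROH = {
          len <- rohMinLen[[m]]
          gRoh(collectPopulationSegments(pop, individuals = ids,
                                         minSnps = minRohSnps,
                                         minLenCm = len), minLenCm = len)
        })
      v <- relValues(G)
      f[k, m] <- mean(v[upper.tri(v)]) / 2
    }
  }
  do.call(rbind, lapply(methods, function(m) {
    # negative mean coancestries (possible for centred VanRaden matrices)
    # are truncated at 0 for the log transform
    s <- deltaFSlope(pmax(f[, m], 0), generations)
    data.frame(method = m, deltaF = s$slope, se = s$se)
  }))
}
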