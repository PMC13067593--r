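#' Build a genetic map
#'
#' @param chrom integer chromosome id per locus (sorted).
#' @param posCm chromosome-local positions in cM.
#' @param chromLengths observable length (cM) of each chromosome.
#' @return a \linkS4class{GeneticMap}.
#' @examples
#' geneticMap(c(1L, 1L, 2L), c(10, 55.5, 3), chromLengths = c(100, 100))
#' @export
geneticMap <- function(chrom = integer(0), posCm = numeric(0), chromLengths) {
  new("GeneticMap", chrom = as.integer(chrom), posCm = as.numeric(posCm),
      chromLengths = as.numeric(chromLengths))
}

#' Genome frame without loci
#'
#' Convenience constructor for a map that only fixes chromosome number and
#' lengths; locus positions are added by the burn-in.
#'
#' @param nChrom number of chromosomes.
#' @param chromCm length of every chromosome in cM.
#' @return a \linkS4class{GeneticMap} with zero loci.
#' @export
genomeMap <- function(nChrom = 3, chromCm = 100) {
  geneticMap(chromLengths = rep(chromCm, nChrom))
}

#' @rdname ocsim-accessors
#' @export
setMethod("nLoci", "GeneticMap", function(x) length(x@chrom))

#' @rdname ocsim-accessors
#' @export
setMethod("totalLength", "GeneticMap", function(x) sum(x@chromLengths))

#' @rdname ocsim-accessors
#' @export
setMethod("chromLengths", "GeneticMap", function(x) x@chromLengths)

#' @rdname ocsim-accessors
#' @export
setMethod("lociChrom", "GeneticMap", function(x) x@chrom)

#' @rdname ocsim-accessors
#' @export
setMethod("lociPosCm", "GeneticMap", function(x) x@posCm)

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap:", length(object@chromLengths), "chromosomes,",
      nLoci(object), "loci, L =", totalLength(object), "cM\n")
})

subsetMap <- function(map, idx) {
  geneticMap(map@chrom[idx], map@posCm[idx], map@chromLengths)
}

#' @rdname ocsim-accessors
#' @export
setMethod("nIndiv", "HaplotypePanel", function(x) ncol(x@haplotypes) %/% 2L)

#' @rdname ocsim-accessors
#' @export
setMethod("nLoci", "HaplotypePanel", function(x) nrow(x@haplotypes))

#' @rdname ocsim-accessors
#' @export
setMethod("haplotypes", "HaplotypePanel", function(x, ...) x@haplotypes)

#' @rdname ocsim-accessors
#' @export
setMethod("alleleFreqs", "HaplotypePanel", function(x, ...) x@freq)

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", ncol(object@haplotypes), "haplotypes x",
      nrow(object@haplotypes), "polymorphic sites (of",
      object@nSitesSimulated, "simulated)\n")
})

setMethod("show", "LociPanels", function(object) {
  cat("LociPanels:", length(object@snpIdx), "SNPs,",
      length(object@neutralIdx), "neutral loci,",
      length(object@qtlIdx), "QTL\n")
})

#' @rdname ocsim-accessors
#' @export
setMethod("nIndiv", "Population", function(x) nrow(x@ped))

#' @rdname ocsim-accessors
#' @export
setMethod("nLoci", "Population", function(x) nrow(x@alleles))

#' @rdname ocsim-accessors
#' @export
setMethod("pedigree", "Population", function(x) x@ped)

#' Extract haplotype columns
#'
#' @param x a Population.
#' @param individuals ids to extract (default all).
#' @param loci row indices (default all).
#' @rdname ocsim-accessors
#' @export
setMethod("haplotypes", "Population", function(x, individuals = NULL,
                                               loci = NULL, ...) {
  cols <- if (is.null(individuals)) seq_len(2L * nIndiv(x)) else
    as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  rows <- if (is.null(loci)) seq_len(nLoci(x)) else loci
  x@alleles[rows, cols, drop = FALSE]
})

#' @rdname ocsim-accessors
#' @export
setMethod("founderLabels", "Population", function(x, individuals = NULL,
                                                  loci = NULL, ...) {
  cols <- if (is.null(individuals)) seq_len(2L * nIndiv(x)) else
    as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  rows <- if (is.null(loci)) seq_len(nLoci(x)) else loci
  x@labels[rows, cols, drop = FALSE]
})

#' @rdname ocsim-accessors
#' @export
setMethod("dosages", "Population", function(x, individuals = NULL,
                                            loci = NULL, ...) {
  ids <- if (is.null(individuals)) seq_len(nIndiv(x)) else individuals
  rows <- if (is.null(loci)) seq_len(nLoci(x)) else loci
  x@alleles[rows, 2L * ids - 1L, drop = FALSE] +
    x@alleles[rows, 2L * ids, drop = FALSE]
})

#' @rdname ocsim-accessors
#' @export
setMethod("tbv", "Population", function(x) x@tbv)

#' @rdname ocsim-accessors
#' @export
setMethod("phenotypes", "Population", function(x) x@phenotype)

#' @rdname ocsim-accessors
#' @export
setMethod("alleleFreqs", "Population", function(x, individuals = NULL,
                                                loci = NULL, ...) {
  d <- dosages(x, individuals = individuals, loci = loci)
  rowMeans(d) / 2
})

setMethod("show", "Population", function(object) {
  g <- range(object@ped$generation)
  cat("Population:", nIndiv(object), "individuals over generations",
      g[1], "to", g[2], ";", nLoci(object), "panel loci\n")
})

#' @rdname ocsim-accessors
#' @export
setMethod("relValues", "RelationshipMatrix", function(x) x@values)

#' @rdname ocsim-accessors
#' @export
setMethod("methodTag", "RelationshipMatrix", function(x) x@method)

#' @rdname ocsim-accessors
#' @export
setMethod("indivIds", "RelationshipMatrix", function(x) x@ids)

#' @rdname ocsim-accessors
#' @export
setMethod("nIndiv", "RelationshipMatrix", function(x) nrow(x@values))

#' Inbreeding coefficients from a relationship matrix (diagonal minus one)
#' @rdname ocsim-accessors
#' @export
setMethod("inbreedingCoef", "RelationshipMatrix",
          function(x) diag(x@values) - 1)

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix [", object@method, "]: ", nrow(object@values), " x ",
      ncol(object@values), ", mean diag = ",
      round(mean(diag(object@values)), 4), "\n", sep = "")
})

#' @rdname ocsim-accessors
#' @export
setMethod("segments", "SegmentSet", function(x) x@segments)

#' @rdname ocsim-accessors
#' @export
setMethod("totalLength", "SegmentSet", function(x) x@L)

setMethod("show", "SegmentSet", function(object) {
  cat("SegmentSet:", nrow(object@segments), "segments over",
      length(object@ids), "individuals, L =", object@L, "cM\n")
})

#' @rdname ocsim-accessors
#' @export
setMethod("contributions", "OCSolution", function(x)
  setNames(x@contributions, x@ids))

setMethod("show", "OCSolution", function(object) {
  cat("OCSolution:", object@nSelected, "of", length(object@contributions),
      "candidates selected; merit =", signif(object@merit, 6),
      "; group coancestry =", signif(object@coancestry, 6),
      if (!object@feasible) "(constraint infeasible)" else "", "\n")
})

#' @rdname ocsim-accessors
#' @export
setMethod("schemeReport", "SchemeResult", function(x) x@report)

#' @rdname ocsim-accessors
#' @export
setMethod("contributions", "SchemeResult", function(x) x@contributions)

setMethod("show", "SchemeResult", function(object) {
  cat("SchemeResult [", object@config$scheme, "]: ",
      nrow(object@report), " generations, seed ", object@seed, "\n", sep = "")
})
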