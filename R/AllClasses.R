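#' @useDynLib ocsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats lm coef cor var rnorm runif setNames complete.cases
#' @importFrom utils write.table read.table head tail
#' @importFrom data.table data.table as.data.table .SD .N
NULL

.datatable.aware <- TRUE

#' Genetic map of panel loci
#'
#' Per-locus chromosome assignment and chromosome-local positions in
#' centimorgans, together with the observable length of each chromosome.
#' The total observable genome length \code{L} (the denominator of the
#' ROH relationship matrix) is the sum of the chromosome lengths.
#'
#' @slot chrom integer chromosome id per locus (non-decreasing).
#' @slot posCm numeric chromosome-local position (cM) per locus, strictly
#'   increasing within chromosome.
#' @slot chromLengths numeric observable length (cM) of every chromosome,
#'   indexed by chromosome id.
#' @export
setClass("GeneticMap",
  representation(chrom = "integer", posCm = "numeric",
                 chromLengths = "numeric"))

setValidity("GeneticMap", function(object) {
  if (length(object@chrom) != length(object@posCm))
    return("chrom and posCm must have equal length")
  if (length(object@chromLengths) < 1 || any(object@chromLengths <= 0))
    return("chromosome lengths must be positive")
  if (length(object@chrom)) {
    if (is.unsorted(object@chrom))
      return("loci must be ordered by chromosome")
    if (any(object@chrom < 1L) ||
        any(object@chrom > length(object@chromLengths)))
      return("chromosome ids out of range")
    for (c in unique(object@chrom)) {
      p <- object@posCm[object@chrom == c]
      if (any(diff(p) <= 0))
        return("positions must be strictly increasing within chromosome")
      if (any(p < 0) || any(p > object@chromLengths[c]))
        return("positions must lie within the chromosome length")
    }
  }
  TRUE
})

#' Panel of phased haplotypes from the historic population
#'
#' @slot haplotypes integer matrix, loci x haplotypes, 0/1 allele codes
#'   (two adjacent columns per individual).
#' @slot map \linkS4class{GeneticMap} for the retained sites.
#' @slot freq numeric frequency of the allele coded 1 at each retained site.
#' @slot nSitesSimulated integer number of candidate sites the burn-in
#'   simulated before dropping non-biallelic ones.
#' @export
setClass("HaplotypePanel",
  representation(haplotypes = "matrix", map = "GeneticMap",
                 freq = "numeric", nSitesSimulated = "integer"))

setValidity("HaplotypePanel", function(object) {
  if (nrow(object@haplotypes) != length(object@freq))
    return("one frequency per retained site required")
  if (nrow(object@haplotypes) != length(object@map@chrom))
    return("map and haplotype matrix disagree on locus count")
  if (length(object@freq) && (any(object@freq <= 0) || any(object@freq >= 1)))
    return("every retained site must be polymorphic (frequency in (0,1))")
  TRUE
})

#' Disjoint SNP / neutral-locus / QTL panels
#'
#' Index sets into the site dimension of a \linkS4class{HaplotypePanel} (and
#' of the \linkS4class{Population} built from it).
#'
#' @slot snpIdx,neutralIdx,qtlIdx integer site indices; pairwise disjoint.
#' @export
setClass("LociPanels",
  representation(snpIdx = "integer", neutralIdx = "integer",
                 qtlIdx = "integer"))

setValidity("LociPanels", function(object) {
  all3 <- c(object@snpIdx, object@neutralIdx, object@qtlIdx)
  if (anyDuplicated(all3)) return("panels must be pairwise disjoint")
  if (length(all3) && any(all3 < 1L)) return("indices must be positive")
  TRUE
})

#' Additive trait architecture
#'
#' QTL effects are scaled at construction so that the variance of true
#' breeding values over the founder-era individuals equals one; the residual
#' variance is then \eqn{(1 - h^2) / h^2}.
#'
#' @slot qtlEffects numeric additive effect per QTL (trait units per copy
#'   of the allele coded 1).
#' @slot h2 numeric narrow-sense heritability in (0, 1].
#' @slot sigmaE2 numeric residual variance.
#' @export
setClass("TraitArchitecture",
  representation(qtlEffects = "numeric", h2 = "numeric", sigmaE2 = "numeric"))

setValidity("TraitArchitecture", function(object) {
  if (object@h2 <= 0 || object@h2 > 1) return("h2 must be in (0, 1]")
  if (object@sigmaE2 < 0) return("residual variance must be non-negative")
  TRUE
})

#' A simulated population with traceable founder alleles
#'
#' Holds every individual generated so far: pedigree, sexes, generation tags,
#' phased allele haplotypes over all panel loci, the parallel founder-origin
#' label haplotypes (recombined with identical breakpoints), true breeding
#' values and phenotypes.  Columns \code{2i - 1} and \code{2i} of the
#' haplotype matrices are individual \code{i}'s paternal and maternal gametes.
#'
#' @slot ped data.frame with columns id, sire, dam, sex (1 = male,
#'   2 = female), generation; parents precede offspring, 0 = unknown parent.
#' @slot alleles integer matrix loci x 2N of 0/1 alleles.
#' @slot labels integer matrix loci x 2N of founder-origin labels.
#' @slot map \linkS4class{GeneticMap} for the panel loci.
#' @slot panels \linkS4class{LociPanels} indexing SNP/neutral/QTL loci.
#' @slot tbv numeric true breeding value per individual.
#' @slot phenotype numeric phenotype per individual (NA until assigned).
#' @export
setClass("Population",
  representation(ped = "data.frame", alleles = "matrix", labels = "matrix",
                 map = "GeneticMap", panels = "LociPanels",
                 tbv = "numeric", phenotype = "numeric"))

setValidity("Population", function(object) {
  n <- nrow(object@ped)
  need <- c("id", "sire", "dam", "sex", "generation")
  if (!all(need %in% names(object@ped)))
    return("pedigree must have id, sire, dam, sex, generation")
  if (ncol(object@alleles) != 2L * n || ncol(object@labels) != 2L * n)
    return("two haplotype columns per individual required")
  if (nrow(object@alleles) != length(object@map@chrom) ||
      nrow(object@labels) != length(object@map@chrom))
    return("haplotype matrices and map disagree on locus count")
  if (length(object@tbv) != n || length(object@phenotype) != n)
    return("tbv and phenotype must have one entry per individual")
  if (!identical(object@ped$id, seq_len(n)))
    return("ids must be 1..N in pedigree order")
  if (any(object@ped$sire >= object@ped$id & object@ped$sire != 0L) ||
      any(object@ped$dam >= object@ped$id & object@ped$dam != 0L))
    return("parents must precede offspring (pedigree must be acyclic)")
  if (!all(object@ped$sex %in% c(1L, 2L)))
    return("sex must be coded 1 (male) or 2 (female)")
  TRUE
})

#' Set of shared haplotype segments (ROH / IBD)
#'
#' Non-overlapping, half-open [startCm, endCm) intervals keyed by ordered
#' haplotype pair, with the observable genome length used as denominator in
#' the ROH relationship matrix.
#'
#' @slot segments data.frame with columns indivA, hapA, indivB, hapB, chrom,
#'   startCm, endCm, nSnps.
#' @slot L numeric total observable genome length in cM.
#' @slot ids integer ids of the individuals the set was collected over.
#' @export
setClass("SegmentSet",
  representation(segments = "data.frame", L = "numeric", ids = "integer"))

setValidity("SegmentSet", function(object) {
  need <- c("indivA", "hapA", "indivB", "hapB", "chrom",
            "startCm", "endCm", "nSnps")
  if (!all(need %in% names(object@segments)))
    return("segment table lacks required columns")
  if (object@L <= 0) return("total map length L must be positive")
  if (nrow(object@segments) &&
      any(object@segments$endCm <= object@segments$startCm))
    return("segments must satisfy endCm > startCm")
  TRUE
})

#' A relationship matrix tagged with its construction method
#'
#' @slot values numeric N x N symmetric matrix.
#' @slot ids integer individual ids (row/column order).
#' @slot method character tag, e.g. "VR_BF", "VR_CF", "IBD", "ROH05", "FGLA".
#' @slot meta list of construction metadata (reference frequencies, minimum
#'   ROH length, pedigree base, ...).
#' @export
setClass("RelationshipMatrix",
  representation(values = "matrix", ids = "integer", method = "character",
                 meta = "list"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (length(object@ids) != nrow(v))
    return("one id per row required")
  if (nrow(v) && max(abs(v - t(v))) > 1e-10)
    return("matrix must be symmetric within 1e-10")
  TRUE
})

#' Segregation indicators inferred from phased SNP data
#'
#' For every non-base individual and each of its two gametes, which of the
#' transmitting parent's haplotypes carried each SNP locus (1 or 2), plus a
#' status flag: 0 = known from a heterozygous parent, 1 = imputed from the
#' nearest known locus on the chromosome, 2 = sampled by a fair coin.
#'
#' @slot pat,mat integer matrices loci x N (NA for base animals).
#' @slot statusPat,statusMat integer matrices loci x N.
#' @slot ids integer individual ids (columns).
#' @slot baseIds integer ids treated as gene-dropping base animals.
#' @export
setClass("SegregationIndicators",
  representation(pat = "matrix", mat = "matrix",
                 statusPat = "matrix", statusMat = "matrix",
                 ids = "integer", baseIds = "integer"))

#' Optimum contribution solution
#'
#' @slot contributions numeric genetic contribution per candidate
#'   (each sex sums to 1/2).
#' @slot sexes integer sex code per candidate.
#' @slot ids integer candidate ids.
#' @slot merit numeric achieved c'g.
#' @slot coancestry numeric achieved group coancestry c'Ac/2.
#' @slot lambda numeric Lagrange multiplier of the coancestry constraint.
#' @slot lambda0 numeric multipliers of the two sex-sum constraints.
#' @slot nSelected integer count of contributions above 1e-9.
#' @slot feasible logical FALSE when even the minimum-coancestry solution
#'   exceeds the constraint (the returned solution is then that minimum).
#' @export
setClass("OCSolution",
  representation(contributions = "numeric", sexes = "integer",
                 ids = "integer", merit = "numeric", coancestry = "numeric",
                 lambda = "numeric", lambda0 = "numeric",
                 nSelected = "integer", feasible = "logical"))

setValidity("OCSolution", function(object) {
  c <- object@contributions
  if (any(c < -1e-8)) return("contributions must be non-negative")
  for (s in c(1L, 2L)) {
    if (abs(sum(c[object@sexes == s]) - 0.5) > 1e-6)
      return("contributions must sum to 1/2 within each sex")
  }
  TRUE
})

#' Result of one selection-scheme replicate
#'
#' @slot report data.frame of per-generation diagnostics.
#' @slot contributions data.frame of per-generation candidate contributions.
#' @slot config list echo of the scheme configuration.
#' @slot seed integer replicate seed.
#' @slot population the final \linkS4class{Population} (all generations), or
#'   NULL when dropped to save memory.
#' @export
setClass("SchemeResult",
  representation(report = "data.frame", contributions = "data.frame",
                 config = "list", seed = "integer", population = "ANY"))
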