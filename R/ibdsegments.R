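#' Detect shared haplotype segments between two haplotypes
#'
#' Scans for maximal runs of consecutive SNPs at which two (error-free,
#' phased) haplotypes carry identical alleles.  A run is reported when it
#' spans at least \code{minSnps} loci and at least \code{minLenCm}
#' centimorgans; runs never cross chromosome boundaries.  Segment endpoints
#' are the map positions of the first and last SNP of the run, interpreted
#' as a half-open interval [startCm, endCm).
#'
#' On error-free phased data these identity-by-state runs proxy identity by
#' descent; the SNP-count and length filters remove most short chance runs.
#'
#' @param hapA,hapB integer allele vectors over the same loci.
#' @param map a \linkS4class{GeneticMap} for those loci.
#' @param minSnps minimum number of consecutive identical SNPs.
#' @param minLenCm minimum segment span in cM.
#' @return data.frame with columns chrom, startCm, endCm, nSnps.
#' @export
detectSharedSegments <- function(hapA, hapB, map, minSnps = 20,
                                 minLenCm = 1) {
  if (length(hapA) != length(hapB))
    stop("haplotypes must have equal length")
  if (length(hapA) != nLoci(map))
    stop("haplotypes and map disagree on locus count")
  m <- cpp_shared_segments(as.integer(hapA), as.integer(hapB),
                           map@chrom, map@posCm,
                           as.integer(minSnps), minLenCm)
  as.data.frame(m)
}

#' Merge overlapping or book-ended segments
#'
#' Coalesces half-open intervals on one chromosome and haplotype pair into
#' their union; [a, b) and [b, c) merge into [a, c).  The covered length
#' never increases.  SNP counts of merged segments are summed as an upper
#' bound (overlapping loci are not double-counted as positions, only in the
#' count column).
#'
#' @param segs data.frame with columns chrom, startCm, endCm, nSnps.
#' @return data.frame of disjoint sorted segments.
#' @export
mergeOverlapping <- function(segs) {
  if (nrow(segs) == 0) return(segs)
  out <- do.call(rbind, lapply(split(segs, segs$chrom), function(s) {
    s <- s[order(s$startCm, s$endCm), , drop = FALSE]
    start <- s$startCm[1]
    end <- s$endCm[1]
    nsnp <- s$nSnps[1]
    res <- list()
    k <- 0L
    for (i in seq_len(nrow(s))[-1]) {
      if (s$startCm[i] <= end) {        # overlap or book-ended
        if (s$endCm[i] > end) end <- s$endCm[i]
        nsnp <- nsnp + s$nSnps[i]
      } else {
        k <- k + 1L
        res[[k]] <- data.frame(chrom = s$chrom[1], startCm = start,
                               endCm = end, nSnps = nsnp)
        start <- s$startCm[i]; end <- s$endCm[i]; nsnp <- s$nSnps[i]
      }
    }
    res[[k + 1L]] <- data.frame(chrom = s$chrom[1], startCm = start,
                                endCm = end, nSnps = nsnp)
    do.call(rbind, res)
  }))
  rownames(out) <- NULL
  out
}

#' Collect shared segments over a whole population
#'
#' For every individual the within-individual haplotype pair (a1, a2) -- the
#' runs of homozygosity -- and for every unordered pair of individuals the
#' four cross combinations (a1,b1), (a1,b2), (a2,b1), (a2,b2), scanned over
#' the SNP panel with the same filters as
#' \code{\link{detectSharedSegments}} and merged per haplotype pair.
#'
#' @param pop a \linkS4class{Population}.
#' @param individuals ids to include (default: all).
#' @param minSnps,minLenCm segment filters.
#' @param loci SNP rows to scan (default: the population's SNP panel).
#' @return a \linkS4class{SegmentSet}; individual indices in the segment
#'   table refer to positions in \code{individuals}.
#' @export
collectPopulationSegments <- function(pop, individuals = NULL, minSnps = 20,
                                      minLenCm = 1, loci = NULL) {
  if (is.null(individuals)) individuals <- pop@ped$id
  if (is.null(loci)) loci <- pop@panels@snpIdx
  haps <- haplotypes(pop, individuals = individuals, loci = loci)
  sub <- subsetMap(pop@map, loci)
  m <- cpp_collect_segments(haps, sub@chrom, sub@posCm,
                            as.integer(minSnps), minLenCm)
  segs <- as.data.frame(m)
  # maximal runs from a single scan are already disjoint per haplotype pair;
  # merging is retained for inputs assembled from external segment files
  new("SegmentSet", segments = segs, L = totalLength(pop@map),
      ids = as.integer(individuals))
}

#' Mean length of segments co-inherited from a shared ancestor
#'
#' Gene-drops a labelled founder haplotype through two independent lineages
#' of \code{depth} Poisson-recombination meioses each and records the maximal
#' intervals over which both descendants still carry the focal founder
#' material.  Classical junction theory predicts exponentially distributed
#' lengths with mean \eqn{1 / (2 \, depth)} Morgan.  The drop uses interval
#' arithmetic (exact under the Haldane model) so that long chromosomes and
#' many lineage pairs are cheap.
#'
#' @param depth meioses per lineage (generations to the common ancestor).
#' @param chromLenCm chromosome length in cM (long relative to the expected
#'   segment length, to limit edge truncation).
#' @param minSegments keep sampling lineage pairs until at least this many
#'   segments are collected.
#' @param batchPairs lineage pairs per batch.
#' @param maxBatches safety cap on batches.
#' @param seed optional integer seed.
#' @return numeric vector of segment lengths in cM.
#' @export
dropSharedSegmentLengths <- function(depth = 10, chromLenCm = 10000,
                                     minSegments = 10000,
                                     batchPairs = 200000L,
                                     maxBatches = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lengths <- numeric(0)
  for (b in seq_len(maxBatches)) {
    lengths <- c(lengths,
                 cpp_shared_ancestral_segments(batchPairs, as.integer(depth),
                                               chromLenCm))
    if (length(lengths) >= minSegments) break
  }
  lengths
}
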