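relMat <- function(values, ids, method, meta = list()) {
  values <- (values + t(values)) / 2
  dimnames(values) <- list(ids, ids)
  new("RelationshipMatrix", values = values, ids = as.integer(ids),
      method = method, meta = meta)
}

#' VanRaden method I genomic relationship matrix
#'
#' \eqn{G = (M - 2P)(M - 2P)' / (2 \sum_i p_i (1 - p_i))} with genotypes
#' centred by the supplied reference allele frequencies (base-population
#' frequencies for the VR_BF variant, the candidates' current frequencies
#' for VR_CF).
#'
#' @param dosages loci x individuals matrix of 0/1/2 dosages.
#' @param refFreqs per-locus reference frequency of the allele coded 1.
#' @param ids individual ids (default 1..N).
#' @param method tag stored on the matrix ("VR_BF" / "VR_CF").
#' @return a \linkS4class{RelationshipMatrix}.
#' @export
gVanRaden <- function(dosages, refFreqs, ids = NULL, method = "VR_BF") {
  if (length(refFreqs) != nrow(dosages))
    stop("one reference frequency per locus required")
  denom <- 2 * sum(refFreqs * (1 - refFreqs))
  if (denom <= 0)
    stop("zero denominator: all reference frequencies are 0 or 1")
  Z <- dosages - 2 * refFreqs
  G <- crossprod(Z) / denom
  if (is.null(ids)) ids <- seq_len(ncol(dosages))
  relMat(G, ids, method, meta = list(refFreqs = refFreqs))
}

#' True identity-by-descent relationship matrix from founder labels
#'
#' The diagonal for individual a is 1 plus the fraction of SNP loci at which
#' a's two founder-origin labels are identical; the off-diagonal for a and b
#' averages the identity fraction over all four gamete combinations
#' (a1,b1), (a1,b2), (a2,b1), (a2,b2) and multiplies by 2/2, exactly as a
#' gametic relationship matrix is assembled.  Since founder labels are
#' uniquely coded per founder gamete, identity of labels is identity by
#' descent relative to the founders.
#'
#' @param pop a \linkS4class{Population} with founder labels.
#' @param individuals ids to include (default all).
#' @param loci loci rows to average over (default the SNP panel).
#' @return a \linkS4class{RelationshipMatrix} with method "IBD".
#' @export
gTrueIbd <- function(pop, individuals = NULL, loci = NULL) {
  if (is.null(individuals)) individuals <- pop@ped$id
  if (is.null(loci)) loci <- pop@panels@snpIdx
  labs <- founderLabels(pop, individuals = individuals, loci = loci)
  if (!length(labs) || anyNA(labs))
    stop("founder labels are missing")
  relMat(cpp_ibd_matrix(labs), individuals, "IBD")
}

#' Per-individual true IBD inbreeding coefficients
#'
#' Fraction of loci homozygous for founder alleles (the diagonal of the true
#' IBD matrix minus one), computed without forming the full matrix.
#'
#' @inheritParams gTrueIbd
#' @return numeric vector named by individual id.
#' @export
ibdInbreeding <- function(pop, individuals = NULL, loci = NULL) {
  if (is.null(individuals)) individuals <- pop@ped$id
  if (is.null(loci)) loci <- pop@panels@snpIdx
  labs <- founderLabels(pop, individuals = individuals, loci = loci)
  setNames(cpp_ibd_inbreeding(labs), individuals)
}

#' Runs-of-homozygosity relationship matrix
#'
#' Diagonal: \eqn{1 + \sum_k L_{seg_k}(a_1, a_2) / L}; off-diagonal:
#' \eqn{[\sum L(a_1,b_1) + \sum L(a_1,b_2) + \sum L(a_2,b_1) +
#' \sum L(a_2,b_2)] / (2L)}, where the sums run over the merged shared
#' segments of each haplotype pair and L is the total observable genome
#' length.
#'
#' @param segset a \linkS4class{SegmentSet} from
#'   \code{\link{collectPopulationSegments}}.
#' @param minLenCm optional minimum segment length recorded in the method
#'   tag (e.g. 5 gives "ROH05").
#' @return a \linkS4class{RelationshipMatrix}.
#' @export
gRoh <- function(segset, minLenCm = NULL) {
  L <- segset@L
  if (L <= 0) stop("total map length L must be positive")
  N <- length(segset@ids)
  G <- matrix(0, N, N)
  diag(G) <- 1
  s <- segset@segments
  if (nrow(s)) {
    # key by unordered individual pair so all four haplotype combinations
    # accumulate together regardless of orientation
    dt <- data.table::data.table(a = pmin(s$indivA, s$indivB),
                                 b = pmax(s$indivA, s$indivB),
                                 len = s$endCm - s$startCm)
    agg <- dt[, list(tot = sum(len)), by = c("a", "b")]
    w <- agg$a == agg$b
    if (any(w))
      G[cbind(agg$a[w], agg$a[w])] <- 1 + agg$tot[w] / L
    if (any(!w)) {
      G[cbind(agg$a[!w], agg$b[!w])] <- agg$tot[!w] / (2 * L)
      G[cbind(agg$b[!w], agg$a[!w])] <- agg$tot[!w] / (2 * L)
    }
  }
  tag <- if (is.null(minLenCm)) "ROH" else sprintf("ROH%02d", round(minLenCm))
  relMat(G, segset@ids, tag, meta = list(minLenCm = minLenCm, L = L))
}

# index into knownPos of the nearest known locus for each query position;
# exact distance ties resolve towards the smaller position
nearestKnown <- function(queryPos, knownPos) {
  j <- findInterval(queryPos, knownPos)
  left <- pmax(j, 1L)
  right <- pmin(j + 1L, length(knownPos))
  dl <- abs(queryPos - knownPos[left])
  dr <- abs(knownPos[right] - queryPos)
  ifelse(dl <= dr, left, right)
}

#' Infer segregation indicators from phased SNP genotypes
#'
#' For every individual born after the designated base generation and each
#' of its two gametes, determines which of the transmitting parent's
#' haplotypes carried each SNP locus.  Where the parent is heterozygous the
#' indicator is read off the phased data ("known"); elsewhere it is imputed
#' from the nearest known locus on the same chromosome (genetic distance,
#' ties towards the smaller position); chromosomes without any known locus
#' receive one fair-coin draw applied to all their loci.
#'
#' @param pop a \linkS4class{Population}.
#' @param baseGeneration generation treated as the gene-dropping base
#'   (its individuals, and any individual with an unknown or pre-base
#'   parent, get fresh base labels).
#' @param loci SNP rows to use (default the SNP panel).
#' @param seed optional integer seed for the fair-coin draws.
#' @return a \linkS4class{SegregationIndicators}.
#' @export
inferSegregationIndicators <- function(pop, baseGeneration = 0L, loci = NULL,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(loci)) loci <- pop@panels@snpIdx
  ped <- pop@ped
  inScope <- ped$generation >= baseGeneration
  ids <- ped$id[inScope]
  sub <- subsetMap(pop@map, loci)
  S <- length(loci)
  isBase <- ped$generation == baseGeneration
  gap <- inScope & ped$generation > baseGeneration &
    (ped$sire == 0L | ped$dam == 0L |
       ped$generation[pmax(ped$sire, 1L)] < baseGeneration |
       ped$generation[pmax(ped$dam, 1L)] < baseGeneration)
  if (any(gap))
    message(sprintf(
      "%d individuals with unknown or pre-base parents treated as base animals",
      sum(gap)))
  baseIds <- ped$id[isBase | gap]
  N <- nrow(ped)
  pat <- matrix(NA_integer_, S, N)
  mat <- matrix(NA_integer_, S, N)
  statusPat <- matrix(NA_integer_, S, N)
  statusMat <- matrix(NA_integer_, S, N)
  A <- pop@alleles[loci, , drop = FALSE]
  chromSplit <- split(seq_len(S), sub@chrom)
  inferSide <- function(ch, p1, p2, who, side) {
    het <- p1 != p2
    bad <- !het & ch != p1
    if (any(bad))
      stop(sprintf(
        "Mendelian inconsistency: individual %d, %s side, locus %d",
        who, side, which(bad)[1]))
    ind <- rep(NA_integer_, S)
    ind[het] <- ifelse(ch[het] == p2[het], 2L, 1L)
    status <- ifelse(het, 0L, 1L)
    for (cc in chromSplit) {
      u <- cc[!het[cc]]
      if (!length(u)) next
      k <- cc[het[cc]]
      if (length(k)) {
        ind[u] <- ind[k[nearestKnown(sub@posCm[u], sub@posCm[k])]]
      } else {
        ind[u] <- if (runif(1) < 0.5) 1L else 2L
        status[u] <- 2L
      }
    }
    list(ind = ind, status = status)
  }
  for (i in ped$id[inScope & !(ped$id %in% baseIds)]) {
    s <- ped$sire[i]; d <- ped$dam[i]
    rs <- inferSide(A[, 2L * i - 1L], A[, 2L * s - 1L], A[, 2L * s],
                    i, "paternal")
    rd <- inferSide(A[, 2L * i], A[, 2L * d - 1L], A[, 2L * d],
                    i, "maternal")
    pat[, i] <- rs$ind; statusPat[, i] <- rs$status
    mat[, i] <- rd$ind; statusMat[, i] <- rd$status
  }
  new("SegregationIndicators", pat = pat, mat = mat,
      statusPat = statusPat, statusMat = statusMat,
      ids = as.integer(ids), baseIds = as.integer(baseIds))
}

#' Linkage-analysis (FGLA) relationship matrix
#'
#' Allocates two unique founder alleles to every base animal and gene-drops
#' them through the pedigree locus by locus, following the known, imputed or
#' sampled segregation indicators; relationships are then computed from the
#' identities of the dropped alleles exactly as in \code{\link{gTrueIbd}},
#' averaged over all loci.  The matrix therefore measures only the identity
#' by descent accumulated since the chosen base.
#'
#' @param pop a \linkS4class{Population}.
#' @param indicators a \linkS4class{SegregationIndicators} from
#'   \code{\link{inferSegregationIndicators}}.
#' @param individuals ids to return the matrix for (default: all in scope).
#' @param loci SNP rows (must match those used for the indicators).
#' @return a \linkS4class{RelationshipMatrix} with method "FGLA".
#' @export
gFgla <- function(pop, indicators, individuals = NULL, loci = NULL) {
  if (is.null(loci)) loci <- pop@panels@snpIdx
  if (is.null(individuals)) individuals <- indicators@ids
  if (!all(individuals %in% indicators@ids))
    stop("requested individuals precede the gene-dropping base")
  S <- length(loci)
  N <- nrow(pop@ped)
  drop <- matrix(NA_integer_, S, 2L * N)
  nb <- length(indicators@baseIds)
  drop[, c(2L * indicators@baseIds - 1L, 2L * indicators@baseIds)] <-
    rep(c(2L * seq_len(nb) - 1L, 2L * seq_len(nb)), each = S)
  rows <- seq_len(S)
  for (i in setdiff(indicators@ids, indicators@baseIds)) {
    s <- pop@ped$sire[i]; d <- pop@ped$dam[i]
    drop[, 2L * i - 1L] <- drop[cbind(rows, 2L * s - 2L + indicators@pat[, i])]
    drop[, 2L * i] <- drop[cbind(rows, 2L * d - 2L + indicators@mat[, i])]
  }
  cols <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  relMat(cpp_ibd_matrix(drop[, cols, drop = FALSE]), individuals, "FGLA",
         meta = list(baseIds = indicators@baseIds))
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' @param ped data.frame with columns id, sire, dam (ids 1..N in order,
#'   0 = unknown parent).
#' @return numeric N x N matrix.
#' @export
pedigreeA <- function(ped) {
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
    if (i > 1) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (s > 0) A[s, j] else rep(0, i - 1L)) +
                      (if (d > 0) A[d, j] else rep(0, i - 1L)))
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  A
}
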