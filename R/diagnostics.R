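#' Drift-based inbreeding from allele-frequency change
#'
#' Per locus \eqn{F_{drift,i} = 2 (q_{t,i} - q_{0,i})^2 / Het_{0,i}} with
#' \eqn{Het_{0,i} = 2 q_{0,i} (1 - q_{0,i})}, averaged across loci.  Loci
#' fixed in generation 0 (\eqn{Het_0 = 0}) are excluded.
#'
#' @param q0,qt allele frequencies at generation 0 and t.
#' @return list with \code{perLocus}, \code{mean} and \code{excluded}
#'   (indices of excluded loci).
#' @export
fDrift <- function(q0, qt) {
  if (length(q0) != length(qt)) stop("q0 and qt must be matched")
  het0 <- 2 * q0 * (1 - q0)
  keep <- het0 > 0
  if (!any(keep)) stop("all loci are fixed in generation 0")
  v <- rep(NA_real_, length(q0))
  v[keep] <- 2 * (qt[keep] - q0[keep])^2 / het0[keep]
  list(perLocus = v, mean = mean(v[keep]), excluded = which(!keep))
}

#' Homozygosity-based inbreeding from heterozygosity loss
#'
#' Per locus \eqn{F_{hom,i} = (Het_{0,i} - Het_{t,i}) / Het_{0,i}}, averaged
#' across loci; negative values indicate heterozygote excess.  \eqn{Het_t}
#' is the observed heterozygote frequency; \eqn{Het_0} the generation-0
#' expected heterozygosity \eqn{2 q_0 (1 - q_0)}.
#'
#' @param het0,hetT per-locus heterozygosities at generation 0 and t.
#' @return list with \code{perLocus}, \code{mean} and \code{excluded}.
#' @export
fHom <- function(het0, hetT) {
  if (length(het0) != length(hetT)) stop("het0 and hetT must be matched")
  keep <- het0 > 0
  if (!any(keep)) stop("all loci are fixed in generation 0")
  v <- rep(NA_real_, length(het0))
  v[keep] <- (het0[keep] - hetT[keep]) / het0[keep]
  list(perLocus = v, mean = mean(v[keep]), excluded = which(!keep))
}

#' Genic variance
#'
#' \eqn{\sigma_a^2 = 2 \sum_i p_i (1 - p_i) a_i^2}, the additive variance
#' expected under linkage and Hardy-Weinberg equilibrium.
#'
#' @param p QTL allele frequencies.
#' @param a additive effects.
#' @return the genic variance.
#' @export
genicVariance <- function(p, a) {
  2 * sum(p * (1 - p) * a^2)
}

#' Variance of true breeding values
#'
#' Sample variance (n - 1 denominator) of the TBVs.
#'
#' @param tbvs numeric vector.
#' @return the variance.
#' @export
tbvVariance <- function(tbvs) {
  if (length(tbvs) < 2) stop("at least 2 individuals required")
  var(tbvs)
}

#' Rate of inbreeding from a coancestry or inbreeding series
#'
#' Ordinary least-squares slope of \eqn{-\log(1 - f_t)} on generation t.
#' When \eqn{f_t = 1 - (1 - \Delta f)^t} with constant \eqn{\Delta f}, the
#' slope recovers \eqn{-\log(1 - \Delta f) \approx \Delta f} exactly.
#'
#' @param f per-generation mean coancestry or inbreeding.
#' @param generations generation index (default 0, 1, ...).
#' @return list with \code{slope} and its standard error \code{se}.
#' @export
deltaFSlope <- function(f, generations = seq_along(f) - 1) {
  if (any(f >= 1))
    stop(sprintf("f reaches 1 at generation %s",
                 generations[which(f >= 1)[1]]))
  y <- -log(1 - f)
  fit <- lm(y ~ generations)
  sm <- suppressWarnings(summary(fit))  # exact series give perfect fits
  list(slope = unname(coef(fit)[2]),
       se = unname(sm$coefficients[2, 2]))
}

#' Lin's concordance correlation coefficient
#'
#' \eqn{CCC = 2 cov(x, y) / (var(x) + var(y) + (\bar{x} - \bar{y})^2)}:
#' agreement with the identity line, penalizing both scale and location
#' shifts relative to the Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @return the concordance correlation.
#' @export
linsCcc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be matched")
  if (length(x) < 2) stop("at least 2 points required")
  vx <- var(x)
  vy <- var(y)
  if (vx + vy == 0) stop("both sequences are constant")
  2 * stats::cov(x, y) / (vx + vy + (mean(x) - mean(y))^2)
}

#' Regression and concordance of an estimated against a true matrix
#'
#' Regresses the estimated relationships on the true values, separately for
#' the diagonal elements (inbreeding) and the upper-triangle off-diagonals
#' (coancestry), reporting intercept, slope, the slope's standard error,
#' Pearson correlation and Lin's concordance correlation coefficient.
#'
#' @param estimate,truth \linkS4class{RelationshipMatrix} objects over the
#'   same individuals in the same order.
#' @return data.frame with rows "diagonal" and "offdiagonal".
#' @export
compareMatrices <- function(estimate, truth) {
  E <- relValues(estimate)
  Tm <- relValues(truth)
  if (!all(dim(E) == dim(Tm))) stop("dimension mismatch")
  up <- upper.tri(E)
  out <- rbind(cbind(set = "diagonal", regRow(diag(Tm), diag(E))),
               cbind(set = "offdiagonal", regRow(Tm[up], E[up])))
  out$method <- methodTag(estimate)
  rownames(out) <- NULL
  out
}

# regression / agreement summary of estimate y on truth x; degenerate
# (constant) inputs yield NA rather than an error
regRow <- function(x, y) {
  fit <- lm(y ~ x)
  cf <- suppressWarnings(summary(fit))$coefficients
  data.frame(
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2]),
    se = if (nrow(cf) >= 2) unname(cf[2, 2]) else NA_real_,
    correlation = suppressWarnings(cor(x, y)),
    ccc = if (var(x) + var(y) > 0) linsCcc(x, y) else NA_real_)
}

#' QTL fixation and loss counts
#'
#' @param q0,qt QTL reference-allele frequencies at generation 0 and t.
#' @return named vector with \code{fixed} (qt = 1) and \code{lost} (qt = 0).
#' @export
qtlFixationCounts <- function(q0, qt) {
  if (length(q0) != length(qt)) stop("q0 and qt must be matched")
  c(fixed = sum(qt == 1), lost = sum(qt == 0))
}

# observed heterozygote frequency per locus over given individuals
observedHet <- function(pop, individuals = NULL, loci = NULL) {
  d <- dosages(pop, individuals = individuals, loci = loci)
  rowMeans(d == 1L)
}
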